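# Small shared helpers: bit twiddling on exact doubles and seed derivation.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Number of bits needed to represent a non-negative integer
#' @param x non-negative integer-valued numeric
#' @return integer bit length (0 for x = 0)
#' @keywords internal
bit_length <- function(x) {
  stopifnot(x >= 0)
  if (x == 0) return(0L)
  as.integer(floor(log2(x)) + 1)
}

#' Integer to bit vector (LSB first)
#' @param x integer-valued numeric, 0 <= x < 2^width, exact below 2^53
#' @param width number of bits
#' @return integer vector of 0/1, least-significant bit first
#' @keywords internal
int_to_bits <- function(x, width) {
  stopifnot(x >= 0, x < 2^width)
  bits <- integer(width)
  for (i in seq_len(width)) {
    bits[i] <- x %% 2
    x <- (x - bits[i]) / 2
  }
  bits
}

#' Bit vector (LSB first) to numeric
#' @param bits integer vector of 0/1
#' @return numeric value (exact while < 2^53)
#' @keywords internal
bits_to_num <- function(bits) {
  sum(bits * 2^(seq_along(bits) - 1))
}

# Exact floored division for integer-valued doubles (both < 2^53).
# floor(num/den) from '/' can be off by one ulp at boundaries; correct it.
fdiv <- function(num, den) {
  stopifnot(den > 0)
  q <- floor(num / den)
  r <- num - q * den
  while (r < 0) { q <- q - 1; r <- r + den }
  while (r >= den) { q <- q + 1; r <- r - den }
  q
}

# Derive a 32-byte PRG seed from an integer seed and a context string, so
# independent protocol roles never share a byte stream.
derive_seed <- function(seed, context) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  payload <- c(charToRaw(context), writeBin(as.integer(seed), raw(), size = 4))
  .sha256_cpp(payload)
}

# Fresh 32 bytes of OS entropy for production (unseeded) runs.
random_seed_bytes <- function() {
  if (file.exists("/dev/urandom")) {
    con <- file("/dev/urandom", "rb")
    on.exit(close(con))
    readBin(con, what = "raw", n = 32L)
  } else {
    # fall back to R's RNG state
    .sha256_cpp(writeBin(stats::runif(8), raw()))
  }
}
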