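# Cleartext reference implementations: exact fixed-point mirrors of the
# statistic circuits (same floor points, same unsigned expansion) and a
# floating-point chi-squared reference.  Intermediates in the chi-squared
# mirror reach 2^64, beyond exact doubles, so a tiny base-2^20 limb
# representation carries the squares and the final floor division.

# --- minimal non-negative big integers: numeric limb vectors, base 2^20 ---
BIG_BASE <- 2^20

big_from <- function(x) {
  stopifnot(x >= 0, x == floor(x), x < 2^53)
  limbs <- numeric(0)
  while (x > 0) {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
  }
  if (length(limbs) == 0) limbs <- 0
  limbs
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    res[i:(i + length(b) - 1)] <- res[i:(i + length(b) - 1)] + a[i] * b
    # normalize eagerly: limb products stay below 2^40, sums below 2^53
    carry <- floor(res / BIG_BASE)
    res <- res - carry * BIG_BASE
    res <- res + c(0, carry[-length(res)])
    if (carry[length(res)] != 0) res <- c(res, carry[length(res)])
  }
  while (any(res >= BIG_BASE)) {
    carry <- floor(res / BIG_BASE)
    res <- res - carry * BIG_BASE
    res <- res + c(0, carry[-length(res)])
    if (carry[length(res)] != 0) res <- c(res, carry[length(res)])
  }
  res
}

big_mul_scalar <- function(a, s) {
  stopifnot(s >= 0, s < BIG_BASE)
  res <- a * s
  carry <- floor(res / BIG_BASE)
  res <- res - carry * BIG_BASE
  while (any(carry != 0)) {
    res <- c(res, 0)[seq_len(max(length(res), length(carry) + 1))]
    add <- c(0, carry)
    res[seq_along(add)] <- res[seq_along(add)] + add
    carry <- floor(res / BIG_BASE)
    res <- res - carry * BIG_BASE
  }
  while (length(res) > 1 && res[length(res)] == 0) res <- res[-length(res)]
  res
}

big_add_scalar <- function(a, s) {
  a[1] <- a[1] + s
  i <- 1
  while (a[i] >= BIG_BASE) {
    carry <- floor(a[i] / BIG_BASE)
    a[i] <- a[i] - carry * BIG_BASE
    if (i == length(a)) a <- c(a, 0)
    a[i + 1] <- a[i + 1] + carry
    i <- i + 1
  }
  a
}

# floor division by a scalar divisor < 2^32, with remainder
big_divmod_scalar <- function(a, d) {
  stopifnot(d > 0, d < 2^32)
  q <- numeric(length(a))
  rem <- 0
  for (i in rev(seq_along(a))) {
    cur <- rem * BIG_BASE + a[i]          # < 2^32 * 2^20 = 2^52: exact
    qi <- floor(cur / d)
    r <- cur - qi * d
    while (r < 0) { qi <- qi - 1; r <- r + d }
    while (r >= d) { qi <- qi + 1; r <- r - d }
    q[i] <- qi
    rem <- r
  }
  list(q = q, rem = rem)
}

# floor division of a big integer by a scalar divisor < 2^32
big_div_scalar <- function(a, d) {
  big_divmod_scalar(a, d)$q
}

big_to_num <- function(a) {
  v <- sum(a * BIG_BASE^(seq_along(a) - 1))
  if (v >= 2^53) stop("big integer exceeds exact double range")
  v
}

#' Cleartext minor allele frequency (exact fixed point and rational)
#'
#' The frequency of the less frequent allele: `min(low, total - low) /
#' total`, with the fixed-point mantissa `floor(min * 2^fpp / total)` --
#' the same floor the circuit takes.
#'
#' @param low_count low-allele copies (0 <= low_count <= total)
#' @param total total allele copies (> 0)
#' @param fpp fixed-point fractional bits
#' @return list with `mantissa`, `value` (= mantissa / 2^fpp) and
#'   `rational` (the exact frequency); `|value - rational| < 2^-fpp`
#' @examples
#' cleartext_maf(4, 10)$rational  # 0.4
#' cleartext_maf(4, 10)$mantissa  # 26214
#' @export
cleartext_maf <- function(low_count, total, fpp = 16) {
  if (total <= 0) stop("total allele copies must be positive")
  if (low_count < 0 || low_count > total) {
    stop("low_count must lie in [0, total]")
  }
  minct <- min(low_count, total - low_count)
  mantissa <- fdiv(minct * 2^fpp, total)
  list(mantissa = mantissa, value = mantissa / 2^fpp,
       rational = minct / total)
}

#' Cleartext chi-squared statistic, exact fixed-point mirror
#'
#' Replicates the circuit's arithmetic decision-for-decision: expected
#' counts floored at scale `2^fpp`, observed counts scaled by `2^fpp`, the
#' per-cell numerator expanded as `obsFP^2 + expFP^2 - 2*obsFP*expFP`
#' (identical to `(obsFP - expFP)^2` in exact arithmetic -- the expansion
#' only matters in-circuit where values are unsigned), one floor division
#' per cell, cells with a zero expected count gated to zero.
#'
#' @param obs integer vector of 4 observed allele counts: case-low,
#'   case-high, control-low, control-high
#' @param fpp fixed-point fractional bits
#' @return list with `mantissa`, `value` (= mantissa / 2^fpp) and
#'   `degenerate` (TRUE when an allele column is empty)
#' @export
cleartext_chi2 <- function(obs, fpp = 16) {
  stopifnot(length(obs) == 4, all(obs >= 0), all(obs == floor(obs)))
  total_case <- obs[1] + obs[2]
  total_control <- obs[3] + obs[4]
  N <- total_case + total_control
  if (N == 0) stop("empty table: N must be positive")
  col_low <- obs[1] + obs[3]
  col_high <- obs[2] + obs[4]
  exps <- expected_counts(total_case, total_control, col_low, col_high, fpp)
  mantissa <- 0
  for (j in seq_len(4)) {
    if (exps[j] == 0) next
    obs_fp <- obs[j] * 2^fpp
    d <- abs(obs_fp - exps[j])            # exact: both below 2^33
    num <- big_mul(big_from(d), big_from(d))
    term <- big_to_num(big_div_scalar(num, exps[j]))
    mantissa <- mantissa + term
  }
  list(mantissa = mantissa, value = mantissa / 2^fpp,
       degenerate = col_low == 0 || col_high == 0)
}

#' Floating-point chi-squared reference
#'
#' Direct real-arithmetic evaluation of
#' `sum_ij (obs_ij - exp_ij)^2 / exp_ij` over the 2x2 group-by-allele
#' table, with `exp_ij = row_i * col_j / N`.  Degenerate (empty-column)
#' tables return 0.
#'
#' @inheritParams cleartext_chi2
#' @return the statistic as a double
#' @export
float_chi2 <- function(obs) {
  stopifnot(length(obs) == 4, all(obs >= 0))
  rows <- c(obs[1] + obs[2], obs[3] + obs[4])
  cols <- c(obs[1] + obs[3], obs[2] + obs[4])
  N <- sum(obs)
  if (N == 0) stop("empty table: N must be positive")
  if (any(cols == 0)) return(0)
  exp_ <- c(rows[1] * cols[1], rows[1] * cols[2],
            rows[2] * cols[1], rows[2] * cols[2]) / N
  sum((obs - exp_)^2 / exp_)
}
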