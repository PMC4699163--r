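# Bit-packing private counts into bounded hexadecimal input blocks and
# decoding fixed-point circuit outputs.
#
# Each genotype consumes one 32-bit word: the high-order 16 bits hold the
# case-group count of the (lexicographically) low allele, the low-order 16
# bits the control-group count.  A block holds at most 250 words -- 8,000
# bits, the runtime's input-size ceiling -- rendered as 2,000 hex characters.
# The first genotype occupies the leftmost 8 hex characters; each word is
# big-endian.  Only the low-allele count travels: the high count is
# reconstructed in-circuit as TOTAL - low.

BLOCK_WORDS <- 250L
BLOCK_BITS <- 8000L

#' Pack one institution's counts into hexadecimal input blocks
#'
#' @param case_counts,control_counts `allele_counts` for this institution
#' @param meta the *reconciled* `study_metadata` (fixes locus order and the
#'   low/high allele per locus)
#' @param block_size maximum genotypes per block (default 250, i.e. 8,000
#'   bits at 32 bits per genotype)
#' @return list of `packed_block` objects, each with `index` (1-based),
#'   `n_words`, and `hex` (uppercase, 8 characters per word)
#' @examples
#' # one genotype, case low-count 100, control low-count 50 -> "00640032"
#' @export
pack_counts <- function(case_counts, control_counts, meta,
                        block_size = BLOCK_WORDS) {
  stopifnot(block_size >= 1, block_size * 32 <= BLOCK_BITS)
  pairs <- meta_pairs(meta)
  loci <- pairs$locus
  idx <- match(loci, attr(case_counts, "loci"))
  if (anyNA(idx)) {
    stop("locus ", loci[which(is.na(idx))[1]],
         " in metadata is missing from the counts")
  }
  if (!identical(attr(case_counts, "loci"), attr(control_counts, "loci"))) {
    stop("case and control counts cover different loci")
  }
  if (meta$total_case > 65535 || meta$total_control > 65535) {
    stop("group totals exceed 65,535 allele copies; counts no longer fit ",
         "the 16-bit packed fields")
  }
  case_low <- unclass(case_counts)[cbind(idx, match(pairs$low, NUCLEOTIDES))]
  ctrl_low <- unclass(control_counts)[cbind(idx, match(pairs$low, NUCLEOTIDES))]
  if (any(case_low >= 65536) || any(ctrl_low >= 65536)) {
    stop("allele count overflows the 16-bit packed field")
  }
  hex_words <- sprintf("%04X%04X", case_low, ctrl_low)
  n <- length(hex_words)
  n_blocks <- ceiling(n / block_size)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    lo <- (b - 1L) * block_size + 1L
    hi <- min(b * block_size, n)
    blocks[[b]] <- new_packed_block(b, paste0(hex_words[lo:hi], collapse = ""))
  }
  blocks
}

new_packed_block <- function(index, hex) {
  stopifnot(nchar(hex) %% 8 == 0, nchar(hex) * 4 <= BLOCK_BITS)
  structure(list(index = as.integer(index), n_words = nchar(hex) %/% 8L,
                 hex = hex),
            class = "packed_block")
}

#' @export
print.packed_block <- function(x, ...) {
  cat("packed_block #", x$index, ": ", x$n_words, " genotypes, ",
      nchar(x$hex) * 4, " bits\n", sep = "")
  invisible(x)
}

#' Unpack a hexadecimal block into (case, control) low-allele counts
#'
#' Inverse of [pack_counts()] for a single block; case-insensitive on read.
#'
#' @param block a `packed_block` or a hex string
#' @return integer matrix with columns `case_low`, `control_low`
#' @export
unpack_block <- function(block) {
  hex <- if (inherits(block, "packed_block")) block$hex else block
  hex <- toupper(trimws(hex))
  if (!grepl("^[0-9A-F]*$", hex)) {
    stop("not hexadecimal input: '",
         substr(gsub("[0-9A-F]", "", hex), 1, 1), "' is not a hex digit")
  }
  if (nchar(hex) %% 8 != 0) {
    stop("hex block length ", nchar(hex),
         " is not a multiple of 8 characters (one 32-bit word per genotype)")
  }
  n <- nchar(hex) %/% 8L
  if (n == 0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("case_low", "control_low"))))
  }
  starts <- (seq_len(n) - 1L) * 8L + 1L
  case_low <- strtoi(substring(hex, starts, starts + 3L), 16L)
  ctrl_low <- strtoi(substring(hex, starts + 4L, starts + 7L), 16L)
  cbind(case_low = case_low, control_low = ctrl_low)
}

#' Write packed blocks as hex files / read one back
#' @param blocks list of `packed_block`
#' @param dir output directory
#' @param prefix filename prefix; files are `<prefix>_<index>.hex`
#' @return character vector of paths (write) or a `packed_block` (read)
#' @export
write_blocks <- function(blocks, dir, prefix = "block") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(blocks, function(b) {
    path <- file.path(dir, sprintf("%s_%04d.hex", prefix, b$index))
    writeLines(b$hex, path)
    path
  }, character(1))
}

#' @rdname write_blocks
#' @param file path of a single hex block file
#' @param index block index to record (parsed from the filename when `NA`)
#' @export
read_block <- function(file, index = NA) {
  hex <- toupper(trimws(paste0(readLines(file), collapse = "")))
  if (is.na(index)) {
    m <- regmatches(basename(file), regexec("_(\\d+)\\.hex$", basename(file)))[[1]]
    index <- if (length(m) == 2) as.integer(m[2]) else 1L
  }
  if (!grepl("^[0-9A-F]*$", hex)) stop("not a hex block file: ", file)
  new_packed_block(index, hex)
}

#' Decode an unsigned fixed-point mantissa to an exact decimal string
#'
#' The value is `mantissa / 2^fpp`.  Because `2^-fpp` has a finite decimal
#' expansion, the rendering is exact; trailing zeros are trimmed so that
#' re-parsing with [parse_fixed_point()] recovers the mantissa losslessly.
#'
#' @param mantissa non-negative integer-valued numeric (vectorised)
#' @param fpp number of fractional bits (default 16)
#' @return character vector of decimal renderings
#' @examples
#' decode_fixed_point(26214, 16)  # "0.399993896484375"
#' decode_fixed_point(65536, 16)  # "1"
#' @export
decode_fixed_point <- function(mantissa, fpp = 16) {
  stopifnot(fpp >= 0, all(mantissa >= 0), all(mantissa == floor(mantissa)))
  vapply(mantissa, function(m) {
    scale <- 2^fpp
    ip <- fdiv(m, scale)
    frac <- m - ip * scale
    int_str <- format(ip, scientific = FALSE)
    if (frac == 0) return(int_str)
    digits <- character(fpp)
    x <- frac
    for (i in seq_len(fpp)) {
      x <- x * 10
      d <- fdiv(x, scale)
      digits[i] <- as.character(d)
      x <- x - d * scale
      if (x == 0) { digits <- digits[seq_len(i)]; break }
    }
    paste0(int_str, ".", paste0(digits, collapse = ""))
  }, character(1))
}

#' Parse an exact decimal string back to a fixed-point mantissa
#'
#' Inverse of [decode_fixed_point()]; errors if the decimal is not exactly
#' representable at the given precision.
#'
#' @param s decimal string(s)
#' @param fpp number of fractional bits
#' @return numeric mantissa(s)
#' @export
parse_fixed_point <- function(s, fpp = 16) {
  vapply(s, function(str) {
    parts <- strsplit(str, ".", fixed = TRUE)[[1]]
    ip <- as.numeric(parts[1])
    m <- ip * 2^fpp
    if (length(parts) == 2) {
      # exact: fold the digit string into limbs, scale by 2^fpp, then undo
      # the power of ten digit by digit, requiring zero remainders
      digits <- as.numeric(strsplit(parts[2], "")[[1]])
      b <- 0
      for (d in digits) b <- big_add_scalar(big_mul_scalar(b, 10), d)
      b <- big_mul(b, big_from(2^fpp))
      for (k in seq_along(digits)) {
        dm <- big_divmod_scalar(b, 10)
        if (dm$rem != 0) {
          stop("'", str, "' is not exactly representable at FPP=", fpp)
        }
        b <- dm$q
      }
      m <- m + big_to_num(b)
    }
    m
  }, numeric(1), USE.NAMES = FALSE)
}

#' Plan block layout, optionally padded to a fixed public size
#'
#' An institution unwilling to disclose even its genotype count can size all
#' computations to a fixed upper bound: padding genotypes are zero-count
#' monomorphic placeholders whose outputs are discarded.
#'
#' @param n_genotypes actual number of genotypes
#' @param pad_to optional public bound (>= `n_genotypes`) to size the layout
#' @param block_size genotypes per block (default 250)
#' @return list with `n_blocks`, `sizes` (genotypes per block), `n_layout`
#'   (the padded count) and `n_pad` (placeholder genotypes appended)
#' @examples
#' padded_block_plan(9330)$n_blocks        # 38
#' padded_block_plan(311, 9330)$n_blocks   # 38
#' @export
padded_block_plan <- function(n_genotypes, pad_to = NULL,
                              block_size = BLOCK_WORDS) {
  stopifnot(n_genotypes >= 0, block_size >= 1)
  n_layout <- n_genotypes
  if (!is.null(pad_to)) {
    if (pad_to < n_genotypes) {
      stop("pad_to (", pad_to, ") is smaller than the actual genotype count (",
           n_genotypes, ")")
    }
    n_layout <- pad_to
  }
  n_blocks <- as.integer(ceiling(n_layout / block_size))
  sizes <- rep(as.integer(block_size), n_blocks)
  if (n_blocks > 0) {
    last <- n_layout - (n_blocks - 1L) * block_size
    sizes[n_blocks] <- as.integer(last)
  }
  list(n_blocks = n_blocks, sizes = sizes, n_layout = n_layout,
       n_pad = n_layout - n_genotypes)
}
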