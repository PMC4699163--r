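# Per-block MAF and chi-squared circuits, parameterised by the public study
# metadata (group totals baked in as circuit constants, FPP fractional bits).
#
# Input binding per genotype: party A contributes a 32-bit word x, party B a
# 32-bit word y (wires allocated LSB first).  The low-order 16 bits of each
# word are the control group's low-allele count, the high-order 16 bits the
# case group's -- exactly the packed-block word layout.
#
# Intermediate words are sized from the public totals: a group total fitting
# tb bits bounds every aggregated count to tb bits, so the expensive
# multiply/divide stages shrink with the study size instead of running at
# the full 16-bit input width.  All truncations below are value-preserving
# under the packing invariant (every private count <= its group total).

#' Build the per-block minor-allele-frequency circuit
#'
#' For each genotype and each group g (control = low 16 input bits, case =
#' high 16): `lowCt_g = x_g + y_g`, `highCt_g = TOTAL_g - lowCt_g`,
#' `minCt_g = min(lowCt_g, highCt_g)`, and
#' `MAF_g = floor(minCt_g * 2^fpp / TOTAL_g)` as an unsigned fixed-point
#' mantissa.  On a tie (`lowCt == highCt`) either branch yields the same
#' frequency; the comparator is strict less-than with the low count as the
#' default.
#'
#' @param n_genotypes genotypes in this block (at most 250)
#' @param meta reconciled `study_metadata` (provides the public totals)
#' @param fpp fixed-point fractional bits (default 16)
#' @return an `mpc_circuit` with outputs `maf_case/<i>` and
#'   `maf_control/<i>` (scale `fpp`), `i` = 1-based genotype index
#' @export
build_maf_circuit <- function(n_genotypes, meta, fpp = 16) {
  check_block_params(n_genotypes, meta, fpp)
  template <- maf_genotype_template(meta$total_case, meta$total_control, fpp)
  replicate_circuit(template, n_genotypes)
}

maf_genotype_template <- function(total_case, total_control, fpp) {
  circ <- circuit_new()
  x <- circuit_inputs(circ, "A", 32)
  y <- circuit_inputs(circ, "B", 32)
  groups <- list(control = list(x[1:16], y[1:16], total_control),
                 case = list(x[17:32], y[17:32], total_case))
  for (g in names(groups)) {
    xs <- groups[[g]][[1]]
    ys <- groups[[g]][[2]]
    total <- groups[[g]][[3]]
    tb <- bit_length(total)
    tot <- cw_const(circ, total, tb)
    low <- cw_add(circ, xs, ys)[seq_len(max(tb, 1))]  # lowCt <= TOTAL
    high <- cw_sub_nonneg(circ, tot, low)
    lt <- cw_less_than(circ, low, high)
    minct <- cw_select(circ, lt, low, high)
    dividend <- cw_shift_left(circ, minct, fpp)
    q <- cw_divmod(circ, dividend, tot)$q
    mark_output(circ, paste0("maf_", g), q[seq_len(fpp)], scale = fpp)
  }
  circuit_finalize(circ)
}

#' Build the per-block chi-squared circuit
#'
#' Per genotype the 2x2 allelic contingency table is aggregated in-circuit:
#' `obs[0], obs[1]` are the case group's low/high allele counts and
#' `obs[2], obs[3]` the control group's.  Column totals and the expected
#' counts `exp[j] = floor(row_j * col_j * 2^fpp / N)` (N the grand total of
#' allele copies) are computed as fixed-point words; both marginals mix the
#' two parties' private counts, so none of this can be precomputed locally.
#' Each cell contributes `floor((obsFP^2 + expFP^2 - 2*obsFP*expFP) /
#' expFP)`: the squared difference is expanded so that no subtraction can
#' go negative in unsigned arithmetic (`obsFP^2 + expFP^2 >= 2*obsFP*expFP`
#' by AM-GM), products are kept at full width, and the single floor division
#' rescales the cell back to scale `fpp`.  The four cells are summed into
#' the statistic.
#'
#' A pooled-monomorphic genotype (an empty allele column) would divide by
#' zero; those cells are gated to zero and a 1-bit `deg/<i>` output flags
#' the genotype as degenerate (chi-squared reported as 0: a monomorphic
#' site carries no association signal).
#'
#' @inheritParams build_maf_circuit
#' @param debug also tag each cell's numerator borrow wire as output
#'   `borrow/<cell>` so tests can assert the unsigned-safety invariant
#' @return an `mpc_circuit` with outputs `chi2/<i>` (scale `fpp`) and
#'   `deg/<i>` (1 bit)
#' @export
build_chi2_circuit <- function(n_genotypes, meta, fpp = 16, debug = FALSE) {
  check_block_params(n_genotypes, meta, fpp)
  template <- chi2_genotype_template(meta$total_case, meta$total_control, fpp,
                                     debug)
  replicate_circuit(template, n_genotypes)
}

chi2_genotype_template <- function(total_case, total_control, fpp,
                                   debug = FALSE) {
  circ <- circuit_new()
  x <- circuit_inputs(circ, "A", 32)
  y <- circuit_inputs(circ, "B", 32)
  tb_case <- bit_length(total_case)
  tb_ctrl <- bit_length(total_control)
  N <- total_case + total_control
  nb <- bit_length(N)

  tot_case <- cw_const(circ, total_case, tb_case)
  tot_ctrl <- cw_const(circ, total_control, tb_ctrl)
  n_const <- cw_const(circ, N, nb)

  obs0 <- cw_add(circ, x[17:32], y[17:32])[seq_len(tb_case)]   # case low
  obs1 <- cw_sub_nonneg(circ, tot_case, obs0)                  # case high
  obs2 <- cw_add(circ, x[1:16], y[1:16])[seq_len(tb_ctrl)]     # control low
  obs3 <- cw_sub_nonneg(circ, tot_ctrl, obs2)                  # control high

  wcol <- max(tb_case, tb_ctrl) + 1L
  col_low <- cw_add(circ, cw_zext(circ, obs0, wcol - 1L),
                    cw_zext(circ, obs2, wcol - 1L))[seq_len(min(wcol, nb))]
  col_high <- cw_add(circ, cw_zext(circ, obs1, wcol - 1L),
                     cw_zext(circ, obs3, wcol - 1L))[seq_len(min(wcol, nb))]

  cells <- list(list(obs0, tot_case, tb_case, col_low),
                list(obs1, tot_case, tb_case, col_high),
                list(obs2, tot_ctrl, tb_ctrl, col_low),
                list(obs3, tot_ctrl, tb_ctrl, col_high))

  chi2 <- NULL
  for (j in seq_along(cells)) {
    obs <- cells[[j]][[1]]
    row_word <- cells[[j]][[2]]
    tb_row <- cells[[j]][[3]]
    col <- cells[[j]][[4]]
    wfp <- tb_row + fpp
    # expected count: floor(row * col * 2^fpp / N), value < row * 2^fpp
    prod <- cw_mul(circ, row_word, col)
    exp_q <- cw_divmod(circ, cw_shift_left(circ, prod, fpp), n_const)$q
    exp_fp <- exp_q[seq_len(wfp)]
    obs_fp <- cw_shift_left(circ, obs, fpp)            # width wfp as well
    o2 <- cw_mul(circ, obs_fp, obs_fp)
    e2 <- cw_mul(circ, exp_fp, exp_fp)
    oe <- cw_mul(circ, obs_fp, exp_fp)
    s <- cw_add(circ, o2, e2)                          # 2*wfp + 1 bits
    t2 <- cw_zext(circ, cw_shift_left(circ, oe, 1), 2L * wfp + 1L)
    num <- cw_sub_nonneg(circ, s, t2)                  # (obs-exp)^2 scaled
    if (debug) {
      mark_output(circ, paste0("borrow/", j), attr(num, "borrow"), 0)
    }
    term_q <- cw_divmod(circ, num, exp_fp)$q
    dz <- cw_eq_zero(circ, exp_fp)
    zero <- cw_const(circ, 0, length(term_q))
    term <- cw_select(circ, dz, zero, term_q)
    chi2 <- if (is.null(chi2)) {
      term
    } else {
      w <- max(length(chi2), length(term))
      cw_add(circ, cw_zext(circ, chi2, w), cw_zext(circ, term, w))
    }
  }
  deg_low <- cw_eq_zero(circ, col_low)
  deg_high <- cw_eq_zero(circ, col_high)
  t <- emit(circ, GATE_XOR, deg_low, deg_high)
  u <- emit(circ, GATE_AND, deg_low, deg_high)
  deg <- emit(circ, GATE_XOR, t, u)
  mark_output(circ, "chi2", chi2, scale = fpp)
  mark_output(circ, "deg", deg, scale = 0)
  circuit_finalize(circ)
}

#' Fixed-point expected counts of the 2x2 allelic table
#'
#' The standard contingency expectation `exp_ij = row_i * col_j / N`,
#' floored at scale `2^fpp`: `exp[j] = floor(row_j * col_j * 2^fpp / N)`.
#' Rows are the case/control totals (public), columns the pooled low/high
#' allele counts.  The decoded expectations sum to N within `4 * 2^-fpp`.
#'
#' @param total_case,total_control group totals in allele copies
#' @param col_low,col_high pooled low/high allele counts
#'   (`col_low + col_high` must equal `total_case + total_control`)
#' @param fpp fixed-point fractional bits
#' @return numeric vector of 4 mantissas (case-low, case-high, control-low,
#'   control-high), scale `fpp`
#' @export
expected_counts <- function(total_case, total_control, col_low, col_high,
                            fpp = 16) {
  N <- total_case + total_control
  if (N <= 0) stop("empty table: N must be positive")
  if (col_low + col_high != N) stop("column totals do not sum to N")
  rows <- c(total_case, total_case, total_control, total_control)
  cols <- c(col_low, col_high, col_low, col_high)
  vapply(seq_len(4), function(j) fdiv(rows[j] * cols[j] * 2^fpp, N),
         numeric(1))
}

check_block_params <- function(n_genotypes, meta, fpp) {
  if (n_genotypes < 1 || n_genotypes > BLOCK_WORDS) {
    stop("a block holds between 1 and ", BLOCK_WORDS, " genotypes")
  }
  if (meta$total_case <= 0 || meta$total_control <= 0) {
    stop("group totals must be positive to build the circuit")
  }
  if (meta$total_case > 65535 || meta$total_control > 65535) {
    stop("group totals exceed the 16-bit input fields")
  }
  if (fpp < 1 || fpp > 32) stop("fpp must be between 1 and 32")
  invisible(TRUE)
}
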