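test_that("MAF circuit reproduces the five-individual worked example", {
  # AA, AG, AA, AG, GG split 3/2: party A holds {AA, AG, AA} (5 'A' copies),
  # party B {AG, GG} (1 'A' copy); pooled lowCt = 6, highCt = 4, minCt = 4
  meta <- test_meta(1, 5, 5)  # 10 allele copies per group
  circ <- build_maf_circuit(1, meta)
  v <- evaluate_plain(circ, word_bits(5, 5), word_bits(1, 1))
  expect_equal(v[["maf_case/1"]], 26214)     # floor(4 * 2^16 / 10)
  expect_equal(v[["maf_control/1"]], 26214)
  expect_equal(round(v[["maf_case/1"]] / 2^16, 1), 0.4)
})

test_that("MAF is 0.5 exactly on a tied locus and 0 on a monomorphic one", {
  meta <- test_meta(1, 10, 10)  # totals 20
  circ <- build_maf_circuit(1, meta)
  tie <- evaluate_plain(circ, word_bits(10, 10), word_bits(0, 0))
  expect_equal(tie[["maf_case/1"]], 2^15)  # 0.5 at FPP=16
  mono <- evaluate_plain(circ, word_bits(0, 20), word_bits(0, 0))
  expect_equal(mono[["maf_case/1"]], 0)
  expect_equal(mono[["maf_control/1"]], 0)
})

test_that("MAF circuit equals the cleartext fixed-point oracle on random counts", {
  set.seed(7)
  for (totals in list(c(10, 10), c(400, 400), c(36, 24))) {
    meta <- gwasmpc:::new_study_metadata("rs1", "A", "G",
                                         totals[1] / 2, totals[2] / 2)
    circ <- build_maf_circuit(1, meta)
    for (i in 1:40) {
      case_low <- sample(0:totals[1], 1)
      ctrl_low <- sample(0:totals[2], 1)
      a_case <- sample(0:case_low, 1)
      a_ctrl <- sample(0:ctrl_low, 1)
      v <- evaluate_plain(circ, word_bits(a_case, a_ctrl),
                          word_bits(case_low - a_case, ctrl_low - a_ctrl))
      expect_equal(v[["maf_case/1"]],
                   cleartext_maf(case_low, totals[1])$mantissa)
      expect_equal(v[["maf_control/1"]],
                   cleartext_maf(ctrl_low, totals[2])$mantissa)
      expect_lte(v[["maf_case/1"]], 2^15)  # MAF <= 0.5 by definition
    }
  }
})

test_that("MAF has minor-allele symmetry: MAF(low) = MAF(total - low)", {
  meta <- test_meta(1, 50, 50)
  circ <- build_maf_circuit(1, meta)
  set.seed(8)
  for (i in 1:25) {
    low <- sample(0:100, 1)
    v1 <- evaluate_plain(circ, word_bits(low, low), word_bits(0, 0))
    v2 <- evaluate_plain(circ, word_bits(100 - low, 100 - low),
                         word_bits(0, 0))
    expect_equal(v1[["maf_case/1"]], v2[["maf_case/1"]])
  }
})

test_that("chi2 circuit: zero on proportional tables, exact on the disjoint table", {
  # perfectly proportional table: case 30/10, control 30/10 -> chi2 = 0
  meta40 <- test_meta(1, 20, 20)
  c40 <- build_chi2_circuit(1, meta40)
  v <- evaluate_plain(c40, word_bits(30, 30), word_bits(0, 0))
  expect_equal(v[["chi2/1"]], 0)
  expect_equal(v[["deg/1"]], 0)

  # case (10, 0), control (0, 10): chi2 = 20 exactly (all exp = 5)
  meta10 <- test_meta(1, 5, 5)
  c10 <- build_chi2_circuit(1, meta10)
  v2 <- evaluate_plain(c10, word_bits(10, 0), word_bits(0, 0))
  decoded <- v2[["chi2/1"]] / 2^16
  expect_lte(abs(decoded - 20), 4 * 2^-12)
  expect_equal(v2[["chi2/1"]], cleartext_chi2(c(10, 0, 0, 10))$mantissa)
  expect_equal(float_chi2(c(10, 0, 0, 10)), 20)
})

test_that("chi2 circuit equals the cleartext fixed-point oracle on random tables", {
  set.seed(9)
  for (totals in list(c(20, 20), c(400, 400), c(50, 30))) {
    meta <- gwasmpc:::new_study_metadata("rs1", "A", "G",
                                         totals[1] / 2, totals[2] / 2)
    circ <- build_chi2_circuit(1, meta)
    for (i in 1:30) {
      case_low <- sample(0:totals[1], 1)
      ctrl_low <- sample(0:totals[2], 1)
      a_case <- sample(0:case_low, 1)
      a_ctrl <- sample(0:ctrl_low, 1)
      v <- evaluate_plain(circ, word_bits(a_case, a_ctrl),
                          word_bits(case_low - a_case, ctrl_low - a_ctrl))
      o <- cleartext_chi2(c(case_low, totals[1] - case_low,
                            ctrl_low, totals[2] - ctrl_low))
      expect_equal(v[["chi2/1"]], o$mantissa)
      expect_equal(v[["deg/1"]], as.numeric(o$degenerate))
    }
  }
})

test_that("chi2 is invariant under allele-label and group swaps", {
  meta <- test_meta(1, 30, 30)  # equal totals so the row swap is well-posed
  circ <- build_chi2_circuit(1, meta)
  set.seed(10)
  for (i in 1:15) {
    case_low <- sample(0:60, 1)
    ctrl_low <- sample(0:60, 1)
    base <- evaluate_plain(circ, word_bits(case_low, ctrl_low),
                           word_bits(0, 0))
    # swap low/high allele labels: low counts become total - low
    lab <- evaluate_plain(circ, word_bits(60 - case_low, 60 - ctrl_low),
                          word_bits(0, 0))
    expect_equal(base[["chi2/1"]], lab[["chi2/1"]])
    # swap case/control rows
    grp <- evaluate_plain(circ, word_bits(ctrl_low, case_low),
                          word_bits(0, 0))
    expect_equal(base[["chi2/1"]], grp[["chi2/1"]])
  }
})

test_that("unsigned safety: the expanded numerator never borrows", {
  meta <- test_meta(1, 15, 10)
  circ <- build_chi2_circuit(1, meta, debug = TRUE)
  set.seed(12)
  for (i in 1:20) {
    case_low <- sample(0:30, 1)
    ctrl_low <- sample(0:20, 1)
    v <- evaluate_plain(circ, word_bits(case_low, ctrl_low), word_bits(0, 0))
    for (j in 1:4) {
      expect_equal(v[[paste0("borrow/", j, "/1")]], 0)
    }
  }
})

test_that("pooled-monomorphic genotypes report chi2 = 0 with the degenerate flag", {
  meta <- test_meta(1, 10, 10)
  circ <- build_chi2_circuit(1, meta)
  v <- evaluate_plain(circ, word_bits(0, 0), word_bits(0, 0))
  expect_equal(v[["chi2/1"]], 0)
  expect_equal(v[["deg/1"]], 1)
  v2 <- evaluate_plain(circ, word_bits(20, 20), word_bits(0, 0))
  expect_equal(v2[["chi2/1"]], 0)
  expect_equal(v2[["deg/1"]], 1)
})

test_that("expected_counts match the contingency expectation exactly", {
  # uniform table: rows (20,20), cols (20,20), N = 40 -> every exp = 10
  expect_equal(expected_counts(20, 20, 20, 20),
               rep(10 * 2^16, 4))
  # rows (10,10), cols (16,4): exp = 8, 2, 8, 2 (integer-exact)
  expect_equal(expected_counts(10, 10, 16, 4),
               c(8, 2, 8, 2) * 2^16)
  # property: decoded expectations sum to N within 4 * 2^-fpp
  set.seed(13)
  for (i in 1:30) {
    tc <- 2 * sample(1:300, 1)
    tt <- 2 * sample(1:300, 1)
    cl <- sample(0:(tc + tt), 1)
    e <- expected_counts(tc, tt, cl, tc + tt - cl)
    expect_lte(abs(sum(e) / 2^16 - (tc + tt)), 4 * 2^-16)
  }
  expect_error(expected_counts(0, 0, 0, 0), "N must be positive")
})

test_that("block circuit construction validates its parameters", {
  meta <- test_meta(1, 5, 5)
  expect_error(build_maf_circuit(0, meta), "between 1 and 250")
  expect_error(build_maf_circuit(251, meta), "between 1 and 250")
  bad <- gwasmpc:::new_study_metadata("rs1", "A", "G", 0, 5)
  expect_error(build_maf_circuit(1, bad), "positive")
})
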