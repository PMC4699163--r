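# The plain evaluator is itself verified here against ordinary integer
# arithmetic (exhaustively at small widths, randomly at full widths); it
# then serves as the oracle for the garbled protocol.

test_that("word primitives match integer arithmetic exhaustively at small widths", {
  for (w in 2:4) {
    circ <- circuit_new()
    a <- circuit_inputs(circ, "A", w)
    b <- circuit_inputs(circ, "B", w)
    s <- cw_add(circ, a, b)
    d <- cw_sub(circ, a, b)
    m <- cw_mul(circ, a, b)
    dv <- cw_divmod(circ, a, b)
    lt <- cw_less_than(circ, a, b)
    sel <- cw_select(circ, lt, a, b)
    ez <- cw_eq_zero(circ, a)
    mark_output(circ, "sum", s); mark_output(circ, "diff", d$diff)
    mark_output(circ, "borrow", d$borrow); mark_output(circ, "prod", m)
    mark_output(circ, "q", dv$q); mark_output(circ, "r", dv$r)
    mark_output(circ, "lt", lt); mark_output(circ, "min", sel)
    mark_output(circ, "ez", ez)
    fc <- circuit_finalize(circ)
    for (x in 0:(2^w - 1)) {
      for (y in 0:(2^w - 1)) {
        v <- evaluate_plain(fc, gwasmpc:::int_to_bits(x, w),
                            gwasmpc:::int_to_bits(y, w))
        expect_equal(v[["sum"]], x + y)
        expect_equal(v[["diff"]], (x - y) %% 2^w)
        expect_equal(v[["borrow"]], as.numeric(x < y))
        expect_equal(v[["prod"]], x * y)
        if (y > 0) {
          expect_equal(v[["q"]], x %/% y)
          expect_equal(v[["r"]], x %% y)
        } else {
          expect_equal(v[["q"]], 2^w - 1)  # all-ones sentinel
          expect_equal(v[["r"]], x)
        }
        expect_equal(v[["lt"]], as.numeric(x < y))
        expect_equal(v[["min"]], min(x, y))
        expect_equal(v[["ez"]], as.numeric(x == 0))
      }
    }
  }
})

test_that("word primitives match integer arithmetic at full widths", {
  set.seed(33)
  circ <- circuit_new()
  a <- circuit_inputs(circ, "A", 16)
  b <- circuit_inputs(circ, "B", 16)
  s <- cw_add(circ, a, b)
  m <- cw_mul(circ, a, b)
  sh <- cw_shift_left(circ, a, 16)
  dv <- cw_divmod(circ, sh, b)
  mark_output(circ, "sum", s); mark_output(circ, "prod", m)
  mark_output(circ, "shift", sh); mark_output(circ, "q", dv$q)
  mark_output(circ, "r", dv$r)
  fc <- circuit_finalize(circ)
  for (i in 1:100) {
    x <- as.numeric(sample(0:65535, 1))
    y <- as.numeric(sample(1:65535, 1))
    v <- evaluate_plain(fc, gwasmpc:::int_to_bits(x, 16),
                        gwasmpc:::int_to_bits(y, 16))
    expect_equal(v[["sum"]], x + y)
    expect_equal(v[["prod"]], x * y)
    expect_equal(v[["shift"]], x * 65536)
    expect_equal(v[["q"]], gwasmpc:::fdiv(x * 65536, y))
    expect_equal(v[["r"]], x * 65536 - gwasmpc:::fdiv(x * 65536, y) * y)
  }
  # boundary: 2^16-1 + 1 keeps the carry bit
  v <- evaluate_plain(fc, gwasmpc:::int_to_bits(65535, 16),
                      gwasmpc:::int_to_bits(1, 16))
  expect_equal(v[["sum"]], 65536)
})

test_that("shift and constants realise the fixed-point scaling", {
  circ <- circuit_new()
  a <- circuit_inputs(circ, "A", 3)
  sh <- cw_shift_left(circ, a, 16)
  k <- cw_const(circ, 10, 4)
  mark_output(circ, "shifted", sh)
  mark_output(circ, "const", k)
  fc <- circuit_finalize(circ)
  v <- evaluate_plain(fc, gwasmpc:::int_to_bits(4, 3), integer(0))
  expect_equal(v[["shifted"]], 262144)  # 4 * 2^16
  expect_equal(v[["const"]], 10)
})

test_that("builder enforces width and ordering constraints", {
  circ <- circuit_new()
  a <- circuit_inputs(circ, "A", 4)
  b <- circuit_inputs(circ, "B", 6)
  expect_error(cw_add(circ, a, b), "width mismatch")
  expect_error(cw_sub(circ, a, b), "width mismatch")
  expect_error(cw_select(circ, a[1], a, b), "width mismatch")
  cw_add(circ, a, a[c(2, 3, 4, 1)])
  expect_error(circuit_inputs(circ, "A", 2), "before the first gate")
})

test_that("gate counts are deterministic given identical parameters", {
  meta <- test_meta(1, 10, 10)
  c1 <- build_maf_circuit(1, meta)
  c2 <- build_maf_circuit(1, meta)
  expect_identical(c1$kind, c2$kind)
  expect_identical(c1$in1, c2$in1)
  expect_identical(c1$in2, c2$in2)
  c3 <- build_chi2_circuit(1, meta)
  c4 <- build_chi2_circuit(1, meta)
  expect_identical(c3$kind, c4$kind)
})

test_that("replicate_circuit concatenates independent copies", {
  meta <- test_meta(3, 10, 10)
  tmpl <- gwasmpc:::maf_genotype_template(20, 20, 16)
  blk <- replicate_circuit(tmpl, 3)
  expect_equal(blk$n_gates, 3 * tmpl$n_gates)
  expect_equal(blk$n_inputs, 3 * tmpl$n_inputs)
  # party A holds all counts, party B contributes zeros
  counts <- cbind(case_low = c(4L, 10L, 0L), control_low = c(6L, 3L, 20L))
  v <- evaluate_plain(blk, block_bits(counts), rep(0L, 96))
  # copy i must equal the template evaluated on genotype i alone
  for (i in 1:3) {
    solo <- evaluate_plain(tmpl, word_bits(counts[i, 1], counts[i, 2]),
                           rep(0L, 32))
    expect_equal(v[[paste0("maf_case/", i)]], solo[["maf_case"]])
    expect_equal(v[[paste0("maf_control/", i)]], solo[["maf_control"]])
    expect_equal(solo[["maf_case"]],
                 cleartext_maf(counts[i, 1], 20)$mantissa)
  }
})

test_that("circuit text serialization round-trips", {
  meta <- test_meta(1, 5, 5)
  circ <- build_maf_circuit(2, meta)
  f <- withr::local_tempfile(fileext = ".circ")
  write_circuit(circ, f)
  back <- read_circuit(f)
  expect_identical(back$kind, circ$kind)
  expect_identical(back$in1, circ$in1)
  expect_identical(back$in2, circ$in2)
  expect_identical(back$inputs_a, circ$inputs_a)
  expect_identical(back$inputs_b, circ$inputs_b)
  expect_equal(length(back$outputs), length(circ$outputs))
  bits_a <- rand_bits(length(circ$inputs_a))
  bits_b <- rand_bits(length(circ$inputs_b))
  expect_equal(evaluate_plain(back, bits_a, bits_b),
               evaluate_plain(circ, bits_a, bits_b))
})

test_that("evaluate_plain validates input sizes", {
  meta <- test_meta(1, 5, 5)
  circ <- build_maf_circuit(1, meta)
  expect_error(evaluate_plain(circ, rep(0L, 31), rep(0L, 32)), "expects")
  expect_error(evaluate_plain(circ, rep(0L, 32), rep(0L, 3)), "expects")
})
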