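test_that("garbling a single AND gate reproduces its truth table", {
  circ <- circuit_new()
  a <- circuit_inputs(circ, "A", 1)
  b <- circuit_inputs(circ, "B", 1)
  o <- gwasmpc:::emit(circ, gwasmpc:::GATE_AND, a, b)
  mark_output(circ, "and", o)
  fc <- circuit_finalize(circ)
  for (x in 0:1) {
    for (y in 0:1) {
      v <- garbled_run(fc, x, y, seed = 99)
      expect_equal(v[["and"]], as.numeric(x & y))
    }
  }
})

test_that("garbling is deterministic in the seed", {
  fc <- random_circuit(4, 4, 60)
  g1 <- garble(fc, 123)
  g2 <- garble(fc, 123)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$label0, g2$label0)
  g3 <- garble(fc, 124)
  expect_false(identical(g1$tables, g3$tables))
})

test_that("garbled evaluation equals plain evaluation on random circuits", {
  set.seed(41)
  for (i in 1:30) {
    fc <- random_circuit(sample(2:6, 1), sample(2:6, 1),
                         sample(20:200, 1))
    bits_a <- rand_bits(length(fc$inputs_a))
    bits_b <- rand_bits(length(fc$inputs_b))
    expect_equal(garbled_run(fc, bits_a, bits_b, seed = i),
                 evaluate_plain(fc, bits_a, bits_b))
  }
})

test_that("a tampered garbled row fails authentication loudly", {
  meta <- test_meta(1, 5, 5)
  circ <- build_maf_circuit(1, meta)
  g <- garble(circ, 17)
  pub <- garbled_public(g, circ)
  gen_l <- input_labels(g, circ, "A", word_bits(5, 5))
  eval_l <- input_labels(g, circ, "B", word_bits(1, 1))
  # corrupt all four rows of the first garbled gate so the active row is
  # certainly among them
  pub$tables[1:96] <- xor(pub$tables[1:96], as.raw(1))
  expect_error(evaluate_garbled(circ, pub, gen_l, eval_l),
               "authentication")
})

test_that("oblivious transfer delivers exactly the chosen message", {
  m0 <- as.raw(1:16)
  m1 <- as.raw(201:216)
  expect_identical(ot_transfer(m0, m1, 0, seed = 5), m0)
  expect_identical(ot_transfer(m0, m1, 1, seed = 5), m1)
  expect_error(ot_transfer(m0, m1[1:8], 0, seed = 5), "equal length")

  # random messages, both branches, batched
  set.seed(44)
  n <- 8
  choices <- rand_bits(n)
  m0s <- as.raw(sample(0:255, 16 * n, replace = TRUE))
  m1s <- as.raw(sample(0:255, 16 * n, replace = TRUE))
  C <- ot_setup(seed = 6)
  r1 <- ot_choose(choices, C, seed = 7)
  m2 <- ot_send(r1$pk0, m0s, m1s, 16, C, seed = 8)
  got <- ot_retrieve(m2, choices, r1$k, 16)
  for (i in seq_len(n)) {
    idx <- (i - 1) * 16 + 1:16
    want <- if (choices[i] == 1) m1s[idx] else m0s[idx]
    expect_identical(got[idx], want)
  }
})

test_that("16 OTs deliver the garbled labels of one input word", {
  meta <- test_meta(1, 5, 5)
  circ <- build_maf_circuit(1, meta)
  g <- garble(circ, 31)
  bits <- word_bits(1, 1)[1:16]
  wires <- circ$inputs_b[1:16]
  m0 <- gwasmpc:::.select_labels_cpp(g$label0, g$label1, wires,
                                     integer(16))
  m1 <- gwasmpc:::.select_labels_cpp(g$label0, g$label1, wires,
                                     rep(1L, 16))
  C <- ot_setup(seed = 1)
  r1 <- ot_choose(bits, C, seed = 2)
  m2 <- ot_send(r1$pk0, m0, m1, 16, C, seed = 3)
  got <- ot_retrieve(m2, bits, r1$k, 16)
  want <- gwasmpc:::.select_labels_cpp(g$label0, g$label1, wires,
                                       as.integer(bits))
  expect_identical(got, want)
})

test_that("a loopback session reproduces the worked MAF example for both parties", {
  meta <- test_meta(1, 5, 5)
  circ <- build_maf_circuit(1, meta)
  s <- mpc_session(circ, word_bits(5, 5), word_bits(1, 1), seed = 2024)
  expect_equal(s$outputs[["maf_case/1"]], 26214)
  expect_equal(round(s$outputs[["maf_case/1"]] / 2^16, 1), 0.4)
  expect_s3_class(s$transcript, "data.frame")
  expect_true(all(s$transcript$bytes > 0))
  # protocol message order is fixed by the state machine
  expect_equal(s$transcript$type,
               c("hello", "hello", "garbled_circuit", "ot_request",
                 "ot_response", "output_labels", "result"))
})

test_that("transcript shape depends on the circuit, never on private counts", {
  meta <- test_meta(1, 10, 10)
  circ <- build_maf_circuit(1, meta)
  s1 <- mpc_session(circ, word_bits(3, 4), word_bits(5, 6), seed = 1)
  s2 <- mpc_session(circ, word_bits(17, 0), word_bits(2, 20), seed = 1)
  expect_identical(s1$transcript[, c("direction", "type", "bytes")],
                   s2$transcript[, c("direction", "type", "bytes")])
})

test_that("chi2 sessions transfer more bytes than MAF at equal genotype count", {
  meta <- test_meta(2, 10, 10)
  maf <- build_maf_circuit(2, meta)
  chi <- build_chi2_circuit(2, meta)
  bits_a <- block_bits(cbind(c(3L, 8L), c(4L, 1L)))
  bits_b <- block_bits(cbind(c(5L, 2L), c(6L, 9L)))
  sm <- mpc_session(maf, bits_a, bits_b, seed = 3)
  sc <- mpc_session(chi, bits_a, bits_b, seed = 3)
  expect_gt(sum(sc$transcript$bytes), sum(sm$transcript$bytes))
})

test_that("garbled chi2 session decodes the disjoint table to 20", {
  meta <- test_meta(1, 5, 5)
  circ <- build_chi2_circuit(1, meta)
  s <- mpc_session(circ, word_bits(10, 0), word_bits(0, 0), seed = 55)
  expect_equal(s$outputs[["chi2/1"]], cleartext_chi2(c(10, 0, 0, 10))$mantissa)
  expect_lte(abs(s$outputs[["chi2/1"]] / 2^16 - 20), 4 * 2^-12)
})

test_that("the parallel runner is order-independent and reports failing blocks", {
  p <- worked_example_parties()
  meta <- reconcile_metadata(p$a$meta, p$b$meta)
  # 4 loci across 2 blocks of 2
  meta4 <- test_meta(4, 5, 5)
  words_a <- cbind(case_low = c(5L, 0L, 7L, 3L),
                   control_low = c(5L, 2L, 1L, 0L))
  words_b <- cbind(case_low = c(1L, 4L, 2L, 6L),
                   control_low = c(1L, 0L, 3L, 2L))
  r1 <- gwasmpc:::run_block_sessions(words_a, words_b, meta4, "maf", 16,
                                     block_size = 2, workers = 1, seed = 10)
  r2 <- gwasmpc:::run_block_sessions(words_a, words_b, meta4, "maf", 16,
                                     block_size = 2, workers = 2, seed = 10)
  expect_identical(r1$results, r2$results)
  expect_length(r1$transcripts, 2)
  for (i in 1:4) {
    expect_equal(r1$results$mantissa[r1$results$locus == meta4$loci$locus[i] &
                                     r1$results$statistic == "maf_case"],
                 cleartext_maf(words_a[i, 1] + words_b[i, 1], 10)$mantissa)
  }

  # a failing block is named in the error
  local_mocked_bindings(
    mpc_session = function(circ, bits_a, bits_b, seed = NULL) {
      if (identical(bits_a, block_bits(words_a[3:4, , drop = FALSE])))
        stop("induced failure")
      list(outputs = evaluate_plain(circ, bits_a, bits_b),
           transcript = NULL)
    },
    .package = "gwasmpc"
  )
  expect_error(
    gwasmpc:::run_block_sessions(words_a, words_b, meta4, "maf", 16,
                                 block_size = 2, workers = 1, seed = 10),
    "block 2 failed"
  )
})

test_that("padding bounds the layout without changing reported results", {
  meta4 <- test_meta(3, 5, 5)
  words_a <- cbind(case_low = c(5L, 0L, 7L), control_low = c(5L, 2L, 1L))
  words_b <- cbind(case_low = c(1L, 4L, 2L), control_low = c(1L, 0L, 3L))
  plain <- gwasmpc:::run_block_sessions(words_a, words_b, meta4, "maf", 16,
                                        block_size = 2, workers = 1,
                                        seed = 4)
  padded <- gwasmpc:::run_block_sessions(words_a, words_b, meta4, "maf", 16,
                                         block_size = 2, workers = 1,
                                         seed = 4, pad_to = 6)
  expect_length(padded$transcripts, 3)  # ceil(6 / 2) sessions
  expect_equal(padded$results$mantissa, plain$results$mantissa)
  expect_equal(nrow(padded$results), nrow(plain$results))
})

test_that("a networked session matches the loopback result", {
  port <- 17000 + (Sys.getpid() %% 4000)
  p <- worked_example_parties()
  dir_a <- withr::local_tempdir()
  write_counts(p$a$case, file.path(dir_a, "case_counts.tsv"))
  write_counts(p$a$control, file.path(dir_a, "control_counts.tsv"))
  write_metadata(p$a$meta, file.path(dir_a, "metadata.json"))
  # the child process must see the same library the package is loaded from
  libs <- paste(deparse(.libPaths()), collapse = "")
  script <- sprintf(
    '.libPaths(%s);
     suppressMessages(library(gwasmpc));
     mine <- gwasmpc:::load_party_dir("%s");
     res <- mpc_serve_generator(%d, mine$case, mine$control, mine$meta,
                                "maf", seed = 12, timeout = 30);
     write_results(res$results, "%s")',
    libs, dir_a, port, file.path(dir_a, "gen_results.tsv"))
  gen_script <- file.path(dir_a, "gen.R")
  writeLines(script, gen_script)
  system2("Rscript", gen_script, stdout = FALSE, stderr = FALSE,
          wait = FALSE)
  res <- NULL
  for (attempt in 1:40) {
    Sys.sleep(0.5)
    res <- tryCatch(
      mpc_connect_evaluator("localhost", port, p$b$case, p$b$control,
                            p$b$meta, "maf", seed = 12, timeout = 30),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(res)) break
  }
  expect_false(is.null(res))
  row <- res$results[res$results$statistic == "maf_case", ]
  expect_equal(row$mantissa, 26214)
  # the generator wrote the same plaintext results
  for (attempt in 1:20) {
    if (file.exists(file.path(dir_a, "gen_results.tsv"))) break
    Sys.sleep(0.25)
  }
  gen_res <- read_results(file.path(dir_a, "gen_results.tsv"))
  expect_equal(gen_res$value[gen_res$statistic == "maf_case"],
               "0.399993896484375")
})
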