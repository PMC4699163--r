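# Yao garbled-circuit protocol between a circuit generator and evaluator.
#
# Garbling scheme: classic four-row tables with point-and-permute.  Each
# wire gets a pair of 128-bit labels with complementary permute flags (the
# low bit of the last byte); each AND/XOR gate's four rows are ordered by
# the input permute flags and encrypted under SHA256(label_a || label_b ||
# gate id) -- 16 bytes mask the output label, 8 bytes authenticate the row,
# so decrypting with wrong keys fails loudly.  NOT gates swap the input
# label pair (no table); CONST gate labels are disclosed by the generator
# (the bit is public).  No free-XOR/half-gates: correctness and
# auditability first.
#
# Evaluator inputs travel by semi-honest Naor-Pinkas style 1-out-of-2
# oblivious transfer over the multiplicative group mod 2^521 - 1.
#
# Output decoding convention: the evaluator returns the output labels to
# the generator, who decodes them (only the generator holds the label->bit
# map) and shares the plaintext statistics back, so both parties end with
# the results.
#
# All protocol randomness comes from a seedable PRG (SHA-256 in counter
# mode) so transcripts are byte-reproducible in tests; unseeded runs draw
# the seed from OS entropy.

PROTOCOL_VERSION <- 1L

#' Garble a circuit
#'
#' Deterministic given the seed: the same circuit and seed produce
#' byte-identical tables and labels.
#'
#' @param circ a finalized `mpc_circuit`
#' @param seed 32-byte raw seed, an integer seed, or `NULL` for OS entropy.
#'   Integer seeds are for tests and reproducibility only -- they make every
#'   wire label predictable to anyone who knows the seed.
#' @return a `garbled_circuit`: `tables` (public), `label0`/`label1`
#'   (generator secret), `n_tables`
#' @export
garble <- function(circ, seed = NULL) {
  stopifnot(inherits(circ, "mpc_circuit"))
  seed_raw <- garble_seed(seed)
  g <- .garble_cpp(circ$kind, circ$in1, circ$in2, circ$n_inputs, seed_raw)
  structure(list(tables = g$tables, label0 = g$label0, label1 = g$label1,
                 n_tables = g$n_tables, n_wires = circ$n_wires),
            class = "garbled_circuit")
}

garble_seed <- function(seed) {
  if (is.null(seed)) {
    random_seed_bytes()
  } else if (is.raw(seed)) {
    stopifnot(length(seed) == 32)
    seed
  } else {
    derive_seed(seed, "garble")
  }
}

#' The public part of a garbling: what the generator transmits
#'
#' Garbled tables plus the active labels of CONST wires (their bits are
#' public circuit structure).
#'
#' @param g a `garbled_circuit`
#' @param circ the underlying `mpc_circuit`
#' @return list with `tables`, `const_wires`, `const_labels`
#' @export
garbled_public <- function(g, circ) {
  const_gates <- which(circ$kind == GATE_CONST)
  const_wires <- circ$n_inputs + const_gates
  const_bits <- circ$in1[const_gates]
  list(tables = g$tables,
       const_wires = as.integer(const_wires),
       const_labels = .select_labels_cpp(g$label0, g$label1,
                                         as.integer(const_wires),
                                         as.integer(const_bits)))
}

#' Active input labels for one party's bits
#' @param g a `garbled_circuit`
#' @param circ the underlying circuit
#' @param party `"A"` or `"B"`
#' @param bits 0/1 vector in manifest order
#' @return raw vector of 16-byte labels, concatenated
#' @export
input_labels <- function(g, circ, party = c("A", "B"), bits) {
  party <- match.arg(party)
  wires <- if (party == "A") circ$inputs_a else circ$inputs_b
  stopifnot(length(bits) == length(wires))
  .select_labels_cpp(g$label0, g$label1, as.integer(wires), as.integer(bits))
}

#' Evaluate a garbled circuit
#'
#' The evaluator's side: given the public garbling, the generator's input
#' labels and its own (OT-delivered) labels, produce the active label of
#' every wire.  Aborts with an error if any garbled row fails
#' authentication (a corrupted circuit or label).
#'
#' @param circ the (public) circuit topology
#' @param pub output of [garbled_public()]
#' @param gen_labels generator input labels (for `circ$inputs_a`)
#' @param eval_labels evaluator input labels (for `circ$inputs_b`)
#' @return raw vector of active labels for all wires
#' @export
evaluate_garbled <- function(circ, pub, gen_labels, eval_labels) {
  active <- raw(circ$n_wires * 16L)
  active <- .scatter_labels_cpp(active, gen_labels, circ$inputs_a)
  active <- .scatter_labels_cpp(active, eval_labels, circ$inputs_b)
  if (length(pub$const_wires) > 0) {
    active <- .scatter_labels_cpp(active, pub$const_labels, pub$const_wires)
  }
  .eval_garbled_cpp(circ$kind, circ$in1, circ$in2, circ$n_inputs,
                    pub$tables, active)
}

#' Extract the output-wire labels from an active-label array
#' @param circ the circuit
#' @param active raw active labels from [evaluate_garbled()]
#' @return raw vector of labels for the concatenated output wires
#' @export
output_labels <- function(circ, active) {
  wires <- unlist(lapply(circ$outputs, `[[`, "wires"))
  out <- raw(length(wires) * 16L)
  for (i in seq_along(wires)) {
    out[(i - 1L) * 16L + 1:16] <- active[(wires[i] - 1L) * 16L + 1:16]
  }
  out
}

#' Decode output labels back to statistic values (generator side)
#' @param g the full `garbled_circuit` (holds the label pairs)
#' @param circ the circuit
#' @param out_labels raw labels returned by the evaluator
#' @return named numeric vector as from [evaluate_plain()]
#' @export
decode_garbled_outputs <- function(g, circ, out_labels) {
  wires <- unlist(lapply(circ$outputs, `[[`, "wires"))
  # re-scatter into a full array so decode can address by wire id
  active <- raw(circ$n_wires * 16L)
  active <- .scatter_labels_cpp(active, out_labels, as.integer(wires))
  bits_all <- .decode_labels_cpp(active, g$label0, g$label1,
                                 as.integer(wires))
  widths <- vapply(circ$outputs, function(o) length(o$wires), integer(1))
  starts <- cumsum(c(0L, widths[-length(widths)]))
  i <- 0L
  decode_output_bits(circ, function(w) {
    i <<- i + 1L
    bits_all[starts[i] + seq_along(w)]
  })
}

#' One-shot garbled evaluation (garble, exchange labels, evaluate, decode)
#'
#' Test/diagnostic convenience running both roles in-process without OT.
#'
#' @param circ a finalized circuit
#' @param bits_a,bits_b the two parties' input bits
#' @param seed garbling seed
#' @return named numeric outputs, as [evaluate_plain()]
#' @export
garbled_run <- function(circ, bits_a, bits_b, seed = NULL) {
  g <- garble(circ, seed)
  pub <- garbled_public(g, circ)
  gen_l <- input_labels(g, circ, "A", bits_a)
  eval_l <- input_labels(g, circ, "B", bits_b)
  active <- evaluate_garbled(circ, pub, gen_l, eval_l)
  decode_garbled_outputs(g, circ, output_labels(circ, active))
}

# ---------------------------------------------------------------------------
# 1-out-of-2 oblivious transfer (Naor-Pinkas style, semi-honest)

#' OT phase functions
#'
#' The sender publishes a group element `C` with unknown discrete log to
#' the receiver ([ot_setup()]).  Per transfer the receiver sends one public
#' key (`PK0`); its choice bit decides whether `PK0` or `C/PK0` is the key
#' it knows the exponent for.  The sender encrypts each message under the
#' corresponding key ([ot_send()]); the receiver can decrypt exactly its
#' chosen one ([ot_retrieve()]).  All functions are batched: `choices` is a
#' 0/1 vector and messages are fixed-length byte strings, concatenated.
#'
#' @param seed 32-byte raw or integer seed (`NULL` for OS entropy)
#' @return `ot_setup`: the 68-byte element `C`
#' @export
ot_setup <- function(seed = NULL) {
  .ot_sender_setup_cpp(ot_seed(seed, "ot-setup"))
}

ot_seed <- function(seed, context) {
  if (is.null(seed)) random_seed_bytes()
  else if (is.raw(seed)) { stopifnot(length(seed) == 32); seed }
  else derive_seed(seed, context)
}

#' @rdname ot_setup
#' @param choices 0/1 integer vector, one choice bit per transfer
#' @param C the sender's setup element
#' @return `ot_choose`: list with `pk0` (public, to the sender) and `k`
#'   (the receiver's secret exponents)
#' @export
ot_choose <- function(choices, C, seed = NULL) {
  .ot_receiver_msg1_cpp(as.integer(choices), C, ot_seed(seed, "ot-recv"))
}

#' @rdname ot_setup
#' @param pk0 the receiver's public keys
#' @param m0,m1 the two message vectors (raw, `n * msg_len` bytes each)
#' @param msg_len bytes per message
#' @return `ot_send`: list with `gr` and ciphertexts `e0`, `e1`
#' @export
ot_send <- function(pk0, m0, m1, msg_len, C, seed = NULL) {
  stopifnot(length(m0) == length(m1))
  if (length(m0) %% msg_len != 0) stop("message length mismatch")
  .ot_sender_msg2_cpp(pk0, m0, m1, as.integer(msg_len), C,
                      ot_seed(seed, "ot-send"))
}

#' @rdname ot_setup
#' @param msg2 the sender's response (list `gr`, `e0`, `e1`)
#' @param k the receiver's secret exponents from [ot_choose()]
#' @return `ot_retrieve`: raw vector of the chosen messages
#' @export
ot_retrieve <- function(msg2, choices, k, msg_len) {
  .ot_receiver_finish_cpp(msg2$gr, msg2$e0, msg2$e1, as.integer(msg_len),
                          as.integer(choices), k)
}

#' Complete 1-out-of-2 transfer of one message pair (loopback convenience)
#' @param m0,m1 equal-length raw messages
#' @param choice 0 or 1
#' @param seed integer seed for both roles (`NULL` for OS entropy)
#' @return the chosen message (raw)
#' @export
ot_transfer <- function(m0, m1, choice, seed = NULL) {
  if (length(m0) != length(m1)) stop("OT messages must have equal length")
  C <- ot_setup(seed)
  r1 <- ot_choose(choice, C, seed)
  m2 <- ot_send(r1$pk0, m0, m1, length(m0), C, seed)
  ot_retrieve(m2, choice, r1$k, length(m0))
}

# ---------------------------------------------------------------------------
# Sessions

circuit_digest <- function(circ) {
  .sha256_cpp(serialize(list(circ$kind, circ$in1, circ$in2, circ$n_inputs,
                             circ$inputs_a, circ$inputs_b, circ$outputs),
                        NULL))
}

msg_bytes <- function(obj) length(serialize(obj, NULL))

transcript_row <- function(direction, type, bytes) {
  data.frame(direction = direction, type = type, bytes = bytes,
             stringsAsFactors = FALSE)
}

#' Run one garbled-circuit session for a single block, both roles in-process
#'
#' Faithfully executes every protocol message (handshake, garbled circuit +
#' generator labels, OT for the evaluator's labels, output-label return,
#' plaintext result) over an in-process loopback, recording a transcript of
#' per-message byte counts.  The transcript's structure depends only on the
#' circuit shape and block plan, never on the private count values.
#'
#' @param circ a finalized `mpc_circuit` (both parties must agree on it)
#' @param bits_a,bits_b the parties' private input bits
#' @param seed integer seed driving all protocol randomness (`NULL` for OS
#'   entropy)
#' @return list with `outputs` (named numeric, as [evaluate_plain()]) and
#'   `transcript` (data.frame: direction, type, bytes)
#' @export
mpc_session <- function(circ, bits_a, bits_b, seed = NULL) {
  tr <- list()
  note <- function(direction, type, obj) {
    tr[[length(tr) + 1L]] <<- transcript_row(direction, type, msg_bytes(obj))
  }
  # -- handshake
  hello <- list(version = PROTOCOL_VERSION, n_gates = circ$n_gates,
                n_inputs = circ$n_inputs, digest = circuit_digest(circ))
  note("gen->eval", "hello", hello)
  note("eval->gen", "hello", hello)

  # -- generator garbles and transmits circuit + own labels + OT setup
  g <- garble(circ, if (is.null(seed)) NULL else derive_seed(seed, "garble"))
  pub <- garbled_public(g, circ)
  gen_l <- input_labels(g, circ, "A", bits_a)
  C <- ot_setup(if (is.null(seed)) NULL else derive_seed(seed, "ot-setup"))
  msg_gc <- list(pub = pub, gen_labels = gen_l, C = C)
  note("gen->eval", "garbled_circuit", msg_gc)

  # -- OT: evaluator requests labels for its input bits
  r1 <- ot_choose(bits_b, C,
                  if (is.null(seed)) NULL else derive_seed(seed, "ot-recv"))
  note("eval->gen", "ot_request", r1$pk0)
  m0 <- .select_labels_cpp(g$label0, g$label1, circ$inputs_b,
                           integer(length(circ$inputs_b)))
  m1 <- .select_labels_cpp(g$label0, g$label1, circ$inputs_b,
                           rep(1L, length(circ$inputs_b)))
  m2 <- ot_send(r1$pk0, m0, m1, 16L, C,
                if (is.null(seed)) NULL else derive_seed(seed, "ot-send"))
  note("gen->eval", "ot_response", m2)
  eval_l <- ot_retrieve(m2, bits_b, r1$k, 16L)

  # -- evaluation and output decoding
  active <- evaluate_garbled(circ, pub, gen_l, eval_l)
  out_l <- output_labels(circ, active)
  note("eval->gen", "output_labels", out_l)
  outputs <- decode_garbled_outputs(g, circ, out_l)
  note("gen->eval", "result", outputs)

  list(outputs = outputs, transcript = do.call(rbind, tr))
}

# ---------------------------------------------------------------------------
# Study-level runner: pack -> per-block sessions -> merged report

# 32 input bits per genotype, LSB first: control low 16, case high 16,
# matching the packed 32-bit word and the circuit templates.
block_input_bits <- function(words) {
  unlist(lapply(seq_len(nrow(words)), function(i) {
    c(int_to_bits(words[i, "control_low"], 16),
      int_to_bits(words[i, "case_low"], 16))
  }))
}

build_block_circuit <- function(statistic, n_genotypes, meta, fpp) {
  switch(statistic,
         maf = build_maf_circuit(n_genotypes, meta, fpp),
         chi2 = build_chi2_circuit(n_genotypes, meta, fpp),
         stop("unknown statistic: ", statistic))
}

#' Run a full two-party study in simulate mode
#'
#' Both institutions' data live in one process (the in-process loopback
#' transport): counts are reconciled, packed into blocks, each block runs
#' an independent garbled-circuit session, and per-locus results are merged
#' in metadata order regardless of completion order.
#'
#' @param party_a,party_b lists with `case`, `control` (`allele_counts`)
#'   and `meta` (`study_metadata`) for each institution
#' @param statistic `"maf"` or `"chi2"`
#' @param fpp fixed-point fractional bits
#' @param block_size genotypes per block (default 250)
#' @param workers maximum concurrent block sessions (forked; results are
#'   identical for any worker count)
#' @param seed integer master seed; block `b` uses a seed derived from
#'   `seed` and `b`, so results do not depend on scheduling
#' @param pad_to optional public genotype-count bound (see
#'   [padded_block_plan()]); placeholder outputs are discarded
#' @return list with `results` (data.frame: locus, statistic, mantissa,
#'   value, degenerate), `transcripts` (per block), `meta` (merged)
#' @export
mpc_run_study <- function(party_a, party_b, statistic = c("maf", "chi2"),
                          fpp = 16, block_size = BLOCK_WORDS, workers = 1,
                          seed = NULL, pad_to = NULL) {
  statistic <- match.arg(statistic)
  meta <- reconcile_metadata(party_a$meta, party_b$meta)
  blocks_a <- pack_counts(party_a$case, party_a$control, meta, block_size)
  blocks_b <- pack_counts(party_b$case, party_b$control, meta, block_size)
  words_a <- do.call(rbind, lapply(blocks_a, unpack_block))
  words_b <- do.call(rbind, lapply(blocks_b, unpack_block))
  run_block_sessions(words_a, words_b, meta, statistic, fpp, block_size,
                     workers, seed, pad_to)
}

run_block_sessions <- function(words_a, words_b, meta, statistic, fpp,
                               block_size, workers, seed, pad_to = NULL) {
  n_real <- nrow(words_a)
  stopifnot(nrow(words_b) == n_real)
  plan <- padded_block_plan(n_real, pad_to, block_size)
  if (plan$n_pad > 0) {
    pad <- matrix(0L, nrow = plan$n_pad, ncol = 2,
                  dimnames = list(NULL, c("case_low", "control_low")))
    words_a <- rbind(words_a, pad)
    words_b <- rbind(words_b, pad)
  }
  # one template circuit per distinct block size
  circs <- list()
  for (n in unique(plan$sizes)) {
    circs[[as.character(n)]] <- build_block_circuit(statistic, n, meta, fpp)
  }
  offsets <- cumsum(c(0L, plan$sizes[-length(plan$sizes)]))
  run_one <- function(b) {
    tryCatch({
      rows <- offsets[b] + seq_len(plan$sizes[b])
      circ <- circs[[as.character(plan$sizes[b])]]
      block_seed <- if (is.null(seed)) NULL else seed + b
      mpc_session(circ,
                  block_input_bits(words_a[rows, , drop = FALSE]),
                  block_input_bits(words_b[rows, , drop = FALSE]),
                  block_seed)
    }, error = function(e) {
      structure(list(block = b, message = conditionMessage(e)),
                class = "gwasmpc_block_failure")
    })
  }
  sessions <- if (workers > 1) {
    parallel::mclapply(seq_len(plan$n_blocks), run_one,
                       mc.cores = workers, mc.preschedule = FALSE)
  } else {
    lapply(seq_len(plan$n_blocks), run_one)
  }
  for (s in sessions) {
    if (inherits(s, "gwasmpc_block_failure") || inherits(s, "try-error")) {
      stop("block ", s$block, " failed: ", s$message)
    }
  }
  results <- merge_block_outputs(sessions, plan, meta, statistic, fpp,
                                 n_real)
  list(results = results,
       transcripts = lapply(sessions, `[[`, "transcript"),
       meta = meta)
}

merge_block_outputs <- function(sessions, plan, meta, statistic, fpp,
                                n_real) {
  loci <- meta$loci$locus
  rows <- list()
  for (b in seq_along(sessions)) {
    out <- sessions[[b]]$outputs
    offset <- if (b == 1) 0L else sum(plan$sizes[seq_len(b - 1L)])
    for (i in seq_len(plan$sizes[b])) {
      gidx <- offset + i
      if (gidx > n_real) next  # padding placeholder: discard
      if (statistic == "maf") {
        for (grp in c("case", "control")) {
          m <- out[[paste0("maf_", grp, "/", i)]]
          rows[[length(rows) + 1L]] <- data.frame(
            locus = loci[gidx], statistic = paste0("maf_", grp),
            mantissa = m, value = decode_fixed_point(m, fpp),
            degenerate = FALSE, stringsAsFactors = FALSE)
        }
      } else {
        m <- out[[paste0("chi2/", i)]]
        deg <- out[[paste0("deg/", i)]] == 1
        rows[[length(rows) + 1L]] <- data.frame(
          locus = loci[gidx], statistic = "chi2",
          mantissa = m, value = decode_fixed_point(m, fpp),
          degenerate = deg, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Networked sessions: length-prefixed frames over TCP

send_frame <- function(con, obj) {
  payload <- serialize(obj, NULL)
  writeBin(length(payload), con, size = 4L, endian = "big")
  writeBin(payload, con)
  flush(con)
  length(payload)
}

recv_frame <- function(con, timeout_msg = "peer closed the connection") {
  len <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (length(len) == 0) stop(timeout_msg)
  payload <- raw(0)
  while (length(payload) < len) {
    chunk <- readBin(con, "raw", n = len - length(payload))
    if (length(chunk) == 0) stop(timeout_msg)
    payload <- c(payload, chunk)
  }
  unserialize(payload)
}

session_config <- function(statistic, fpp, block_size, n_genotypes) {
  list(version = PROTOCOL_VERSION, statistic = statistic, fpp = fpp,
       block_size = block_size, n_genotypes = n_genotypes)
}

check_handshake <- function(mine, theirs) {
  for (f in c("version", "statistic", "fpp", "block_size", "n_genotypes")) {
    if (!identical(mine[[f]], theirs[[f]])) {
      stop("handshake mismatch on '", f, "': local ", mine[[f]],
           " vs peer ", theirs[[f]])
    }
  }
}

#' Run a networked two-party session (generator role)
#'
#' Listens on `port`, exchanges public metadata with the evaluator,
#' reconciles it (generator metadata first, so both sides derive identical
#' merged metadata), then runs one garbled-circuit session per block over
#' the connection.  Blocks are processed sequentially over the single
#' connection; use simulate mode ([mpc_run_study()]) for parallel blocks.
#'
#' @param port TCP port to listen on (generator) / connect to (evaluator)
#' @param case_counts,control_counts this institution's `allele_counts`
#' @param meta this institution's local `study_metadata`
#' @param statistic `"maf"` or `"chi2"`
#' @param fpp fixed-point fractional bits
#' @param block_size genotypes per block
#' @param seed integer seed (`NULL` for OS entropy)
#' @param timeout connection timeout in seconds
#' @return list with `results`, `transcripts`, `meta` as [mpc_run_study()]
#' @export
mpc_serve_generator <- function(port, case_counts, control_counts, meta,
                                statistic = c("maf", "chi2"), fpp = 16,
                                block_size = BLOCK_WORDS, seed = NULL,
                                timeout = 60) {
  statistic <- match.arg(statistic)
  con <- socketConnection(host = "localhost", port = port, server = TRUE,
                          blocking = TRUE, open = "a+b", timeout = timeout)
  on.exit(close(con))
  # metadata exchange (public by design)
  send_frame(con, list(role = "generator", meta = meta,
                       statistic = statistic, fpp = fpp,
                       block_size = block_size))
  peer <- recv_frame(con)
  if (!identical(peer$role, "evaluator")) stop("peer is not an evaluator")
  merged <- reconcile_metadata(meta, peer$meta)
  cfg <- session_config(statistic, fpp, block_size, nrow(merged$loci))
  send_frame(con, cfg)
  check_handshake(cfg, recv_frame(con))

  blocks <- pack_counts(case_counts, control_counts, merged, block_size)
  words <- do.call(rbind, lapply(blocks, unpack_block))
  plan <- padded_block_plan(nrow(words), NULL, block_size)
  sessions <- vector("list", plan$n_blocks)
  offsets <- cumsum(c(0L, plan$sizes[-length(plan$sizes)]))
  for (b in seq_len(plan$n_blocks)) {
    circ <- build_block_circuit(statistic, plan$sizes[b], merged, fpp)
    rows <- offsets[b] + seq_len(plan$sizes[b])
    bits_a <- block_input_bits(words[rows, , drop = FALSE])
    block_seed <- if (is.null(seed)) NULL else seed + b
    tr <- list()
    note <- function(direction, type, bytes) {
      tr[[length(tr) + 1L]] <<- transcript_row(direction, type, bytes)
    }
    g <- garble(circ, if (is.null(block_seed)) NULL
                      else derive_seed(block_seed, "garble"))
    pub <- garbled_public(g, circ)
    gen_l <- input_labels(g, circ, "A", bits_a)
    C <- ot_setup(if (is.null(block_seed)) NULL
                  else derive_seed(block_seed, "ot-setup"))
    msg <- list(pub = pub, gen_labels = gen_l, C = C,
                digest = circuit_digest(circ))
    note("gen->eval", "garbled_circuit", send_frame(con, msg))
    pk0 <- recv_frame(con)
    note("eval->gen", "ot_request", msg_bytes(pk0))
    m0 <- .select_labels_cpp(g$label0, g$label1, circ$inputs_b,
                             integer(length(circ$inputs_b)))
    m1 <- .select_labels_cpp(g$label0, g$label1, circ$inputs_b,
                             rep(1L, length(circ$inputs_b)))
    m2 <- ot_send(pk0, m0, m1, 16L, C,
                  if (is.null(block_seed)) NULL
                  else derive_seed(block_seed, "ot-send"))
    note("gen->eval", "ot_response", send_frame(con, m2))
    out_l <- recv_frame(con)
    note("eval->gen", "output_labels", msg_bytes(out_l))
    outputs <- decode_garbled_outputs(g, circ, out_l)
    note("gen->eval", "result", send_frame(con, outputs))
    sessions[[b]] <- list(outputs = outputs,
                          transcript = do.call(rbind, tr))
  }
  results <- merge_block_outputs(sessions, plan, merged, statistic, fpp,
                                 nrow(words))
  list(results = results,
       transcripts = lapply(sessions, `[[`, "transcript"),
       meta = merged)
}

#' @rdname mpc_serve_generator
#' @param host generator's host name
#' @export
mpc_connect_evaluator <- function(host, port, case_counts, control_counts,
                                  meta, statistic = c("maf", "chi2"),
                                  fpp = 16, block_size = BLOCK_WORDS,
                                  seed = NULL, timeout = 60) {
  statistic <- match.arg(statistic)
  con <- socketConnection(host = host, port = port, blocking = TRUE,
                          open = "a+b", timeout = timeout)
  on.exit(close(con))
  peer <- recv_frame(con, "generator did not respond")
  if (!identical(peer$role, "generator")) stop("peer is not a generator")
  send_frame(con, list(role = "evaluator", meta = meta,
                       statistic = statistic, fpp = fpp,
                       block_size = block_size))
  peer_cfg <- recv_frame(con)
  merged <- reconcile_metadata(peer$meta, meta)  # generator's metadata first
  cfg <- session_config(statistic, fpp, block_size, nrow(merged$loci))
  send_frame(con, cfg)
  check_handshake(cfg, peer_cfg)

  blocks <- pack_counts(case_counts, control_counts, merged, block_size)
  words <- do.call(rbind, lapply(blocks, unpack_block))
  plan <- padded_block_plan(nrow(words), NULL, block_size)
  sessions <- vector("list", plan$n_blocks)
  offsets <- cumsum(c(0L, plan$sizes[-length(plan$sizes)]))
  for (b in seq_len(plan$n_blocks)) {
    circ <- build_block_circuit(statistic, plan$sizes[b], merged, fpp)
    rows <- offsets[b] + seq_len(plan$sizes[b])
    bits_b <- block_input_bits(words[rows, , drop = FALSE])
    block_seed <- if (is.null(seed)) NULL else seed + b
    msg <- recv_frame(con)
    if (!identical(as.raw(msg$digest), as.raw(circuit_digest(circ)))) {
      stop("circuit digest mismatch in block ", b,
           ": parties built different circuits")
    }
    r1 <- ot_choose(bits_b, msg$C,
                    if (is.null(block_seed)) NULL
                    else derive_seed(block_seed, "ot-recv"))
    send_frame(con, r1$pk0)
    m2 <- recv_frame(con)
    eval_l <- ot_retrieve(m2, bits_b, r1$k, 16L)
    active <- evaluate_garbled(circ, msg$pub, msg$gen_labels, eval_l)
    send_frame(con, output_labels(circ, active))
    outputs <- recv_frame(con)
    sessions[[b]] <- list(outputs = outputs, transcript = NULL)
  }
  results <- merge_block_outputs(sessions, plan, merged, statistic, fpp,
                                 nrow(words))
  list(results = results, transcripts = NULL, meta = merged)
}
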