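# Boolean-circuit intermediate representation and unsigned word arithmetic.
#
# Gate basis: AND, XOR, NOT, CONST (OR is desugared as x XOR y XOR (x AND y)).
# Wires are numbered in creation order: input wires first (1..n_inputs),
# then one output wire per gate, so topological validity reduces to every
# gate reading only lower-numbered wires.  Words ("WordRef") are integer
# vectors of wire ids, least-significant bit first.
#
# All arithmetic is unsigned.  Primitives are emitted in vectorised batches
# (gate and wire ids are computed arithmetically before appending), so
# building circuits with millions of gates costs seconds, not minutes.

GATE_AND <- 1L
GATE_XOR <- 2L
GATE_NOT <- 3L
GATE_CONST <- 4L
GATE_NAMES <- c("AND", "XOR", "NOT", "CONST")

#' Create an empty circuit builder
#'
#' @return a mutable circuit builder (class `circuit_builder`)
#' @seealso [circuit_inputs()], [circuit_finalize()], word-level builders
#'   [cw_add()], [cw_sub()], [cw_mul()], [cw_divmod()], [cw_less_than()],
#'   [cw_select()], [cw_shift_left()], [cw_const()]
#' @export
circuit_new <- function() {
  env <- new.env(parent = emptyenv())
  env$kind <- integer(1024)
  env$in1 <- integer(1024)
  env$in2 <- integer(1024)
  env$n_gates <- 0L
  env$n_inputs <- 0L
  env$n_wires <- 0L
  env$inputs_a <- integer(0)
  env$inputs_b <- integer(0)
  env$outputs <- list()
  class(env) <- "circuit_builder"
  env
}

#' Allocate input wires for one party
#'
#' Input wires must all be allocated before the first gate is emitted (the
#' wire numbering convention places inputs first).
#'
#' @param circ a circuit builder
#' @param party `"A"` (generator) or `"B"` (evaluator)
#' @param n number of bits
#' @return integer vector of wire ids (a WordRef if interpreted LSB-first)
#' @export
circuit_inputs <- function(circ, party = c("A", "B"), n) {
  party <- match.arg(party)
  if (circ$n_gates > 0) {
    stop("all input wires must be allocated before the first gate")
  }
  wires <- circ$n_wires + seq_len(n)
  circ$n_wires <- circ$n_wires + as.integer(n)
  circ$n_inputs <- circ$n_wires
  if (party == "A") {
    circ$inputs_a <- c(circ$inputs_a, wires)
  } else {
    circ$inputs_b <- c(circ$inputs_b, wires)
  }
  wires
}

# Core batch emitter: appends length(kind) gates, returns their output wires.
emit <- function(circ, kind, in1, in2 = integer(length(kind))) {
  n <- length(kind)
  if (n == 0) return(integer(0))
  need <- circ$n_gates + n
  if (need > length(circ$kind)) {
    newlen <- max(2L * length(circ$kind), need)
    length(circ$kind) <- newlen
    length(circ$in1) <- newlen
    length(circ$in2) <- newlen
  }
  idx <- circ$n_gates + seq_len(n)
  circ$kind[idx] <- kind
  circ$in1[idx] <- in1
  circ$in2[idx] <- in2
  circ$n_gates <- circ$n_gates + n
  out <- circ$n_wires + seq_len(n)
  circ$n_wires <- circ$n_wires + n
  out
}

# The wire id the next emitted gate will drive (used by batch primitives to
# reference gates within the same batch).
peek_wire <- function(circ) circ$n_wires

#' Embed a public constant as a word of CONST gates
#' @param circ circuit builder
#' @param value non-negative integer-valued numeric, `value < 2^width`
#' @param width word width in bits
#' @return WordRef (LSB first)
#' @export
cw_const <- function(circ, value, width) {
  bits <- int_to_bits(value, width)
  emit(circ, rep(GATE_CONST, width), bits)
}

#' Ripple-carry addition: returns `a + b` as a `(w+1)`-bit word
#'
#' The carry-out is retained as the top bit; truncate with `[seq_len(w)]`
#' if the caller can bound the sum.
#'
#' @param circ circuit builder
#' @param a,b WordRefs of equal width
#' @return WordRef of width `w + 1`
#' @export
cw_add <- function(circ, a, b) {
  w <- length(a)
  if (length(b) != w) stop("cw_add: width mismatch (", w, " vs ", length(b), ")")
  c0 <- cw_const(circ, 0, 1)
  # per bit: t1 = a^b ; s = t1^c ; t2 = a&b ; t3 = t1&c ; c' = t2^t3
  start <- peek_wire(circ)
  t1 <- start + 5 * (seq_len(w) - 1) + 1
  s  <- t1 + 1
  t2 <- t1 + 2
  t3 <- t1 + 3
  cc <- t1 + 4
  cprev <- c(c0, cc[-w])
  kind <- rep(c(GATE_XOR, GATE_XOR, GATE_AND, GATE_AND, GATE_XOR), w)
  in1 <- as.integer(rbind(a, t1, a, t1, t2))
  in2 <- as.integer(rbind(b, cprev, b, cprev, t3))
  emit(circ, kind, in1, in2)
  c(s, cc[w])
}

#' Borrow subtraction: `a - b` with the borrow-out wire exposed
#'
#' Callers relying on `a >= b` can assert the borrow wire is 0 under plain
#' evaluation; the difference word is `a - b mod 2^w`.
#'
#' @param circ circuit builder
#' @param a,b WordRefs of equal width
#' @return list with `diff` (WordRef, width w) and `borrow` (single wire)
#' @export
cw_sub <- function(circ, a, b) {
  w <- length(a)
  if (length(b) != w) stop("cw_sub: width mismatch (", w, " vs ", length(b), ")")
  b0 <- cw_const(circ, 0, 1)
  # t1 = a^b ; d = t1^bin ; na = !a ; t2 = na&b ; nt1 = !t1 ; t3 = nt1&bin ;
  # bout = t2^t3   (the two borrow terms are mutually exclusive)
  start <- peek_wire(circ)
  t1  <- start + 7 * (seq_len(w) - 1) + 1
  d   <- t1 + 1
  na  <- t1 + 2
  t2  <- t1 + 3
  nt1 <- t1 + 4
  t3  <- t1 + 5
  bo  <- t1 + 6
  bprev <- c(b0, bo[-w])
  kind <- rep(c(GATE_XOR, GATE_XOR, GATE_NOT, GATE_AND, GATE_NOT, GATE_AND,
                GATE_XOR), w)
  in1 <- as.integer(rbind(a, t1, a, na, t1, nt1, t2))
  in2 <- as.integer(rbind(b, bprev, 0L, b, 0L, bprev, t3))
  emit(circ, kind, in1, in2)
  list(diff = d, borrow = bo[w])
}

#' Subtraction under a structural `a >= b` guarantee
#'
#' @inheritParams cw_sub
#' @return WordRef of width w; the borrow wire is attached as attribute
#'   `"borrow"` so tests can assert it evaluates to 0
#' @export
cw_sub_nonneg <- function(circ, a, b) {
  r <- cw_sub(circ, a, b)
  structure(r$diff, borrow = r$borrow)
}

#' Shift-and-add multiplication at full width
#' @param circ circuit builder
#' @param a,b WordRefs (widths may differ)
#' @return WordRef of width `length(a) + length(b)`
#' @export
cw_mul <- function(circ, a, b) {
  wa <- length(a)
  wb <- length(b)
  # partial product for bit 1 of a
  acc <- emit(circ, rep(GATE_AND, wb), b, rep(a[1], wb))
  if (wa == 1) return(acc)
  for (i in 2:wa) {
    pp <- emit(circ, rep(GATE_AND, wb), b, rep(a[i], wb))
    lowbits <- acc[seq_len(i - 1)]
    high <- cw_zext(circ, acc[i:length(acc)], wb)  # width wb - 1 -> wb
    sum_ <- cw_add(circ, high, pp)                 # width wb + 1
    acc <- c(lowbits, sum_)                        # width wb + i
  }
  acc
}

#' Zero-extend a word to a wider width
#' @param circ circuit builder
#' @param a WordRef
#' @param width target width (`>= length(a)`)
#' @return WordRef of the target width
#' @export
cw_zext <- function(circ, a, width) {
  if (width < length(a)) stop("cw_zext: target narrower than word")
  if (width == length(a)) return(a)
  c(a, cw_const(circ, 0, width - length(a)))
}

#' Left shift by a public constant (widens the word)
#' @param circ circuit builder
#' @param a WordRef
#' @param k shift amount in bits
#' @return WordRef of width `length(a) + k`
#' @export
cw_shift_left <- function(circ, a, k) {
  if (k == 0) return(a)
  c(cw_const(circ, 0, k), a)
}

#' Unsigned comparison: a single wire carrying `[a < b]`
#' @param circ circuit builder
#' @param a,b WordRefs (zero-extended to a common width)
#' @return single wire id
#' @export
cw_less_than <- function(circ, a, b) {
  w <- max(length(a), length(b))
  r <- cw_sub(circ, cw_zext(circ, a, w), cw_zext(circ, b, w))
  r$borrow
}

#' Two-way multiplexer: `cond ? a : b` per bit
#' @param circ circuit builder
#' @param cond single wire id
#' @param a,b WordRefs of equal width
#' @return WordRef
#' @export
cw_select <- function(circ, cond, a, b) {
  w <- length(a)
  if (length(b) != w) stop("cw_select: width mismatch")
  start <- peek_wire(circ)
  t <- start + 3 * (seq_len(w) - 1) + 1
  u <- t + 1
  o <- t + 2
  kind <- rep(c(GATE_XOR, GATE_AND, GATE_XOR), w)
  in1 <- as.integer(rbind(a, t, u))
  in2 <- as.integer(rbind(b, rep(cond, w), b))
  emit(circ, kind, in1, in2)
  o
}

#' Is the word all-zero? (single wire)
#' @param circ circuit builder
#' @param a WordRef
#' @return single wire id carrying `[a == 0]`
#' @export
cw_eq_zero <- function(circ, a) {
  nz <- a[1]
  for (i in seq_along(a)[-1]) {
    # or(x, y) = x ^ y ^ (x & y)
    t <- emit(circ, GATE_XOR, nz, a[i])
    u <- emit(circ, GATE_AND, nz, a[i])
    nz <- emit(circ, GATE_XOR, t, u)
  }
  emit(circ, GATE_NOT, nz)
}

#' Restoring division with floor semantics
#'
#' Computes `num = q * den + r` with `0 <= r < den` for `den > 0`.  The
#' denominator is structurally nonzero at every call site in the statistic
#' circuits (it is a public total or an expected count guarded by a zero
#' test); division by zero is nonetheless total: it yields an all-ones
#' quotient and a remainder equal to the low `length(den)+1` bits of `num`.
#'
#' @param circ circuit builder
#' @param num dividend WordRef (width n)
#' @param den divisor WordRef (width m)
#' @return list with `q` (WordRef, width n) and `r` (WordRef, width m+1)
#' @export
cw_divmod <- function(circ, num, den) {
  n <- length(num)
  m <- length(den)
  rw <- m + 1L
  r <- cw_const(circ, 0, rw)
  den_ext <- cw_zext(circ, den, rw)
  q <- integer(n)
  for (i in rev(seq_len(n))) {
    r_shift <- c(num[i], r[seq_len(rw - 1)])  # r < den keeps the top bit free
    s <- cw_sub(circ, r_shift, den_ext)
    qbit <- emit(circ, GATE_NOT, s$borrow)
    r <- cw_select(circ, qbit, s$diff, r_shift)
    q[i] <- qbit
  }
  list(q = q, r = r)
}

#' Tag a word as a named circuit output
#' @param circ circuit builder
#' @param name output name (e.g. `"maf_case/1"`)
#' @param wires WordRef (LSB first)
#' @param scale fixed-point scale: the decoded value is `word / 2^scale`
#' @return invisibly, the builder
#' @export
mark_output <- function(circ, name, wires, scale = 0) {
  circ$outputs[[length(circ$outputs) + 1L]] <-
    list(name = name, wires = as.integer(wires), scale = as.integer(scale))
  invisible(circ)
}

#' Freeze a builder into an immutable, validated circuit
#'
#' Checks topological validity (every gate reads lower-numbered wires), wire
#' range, party manifests (disjoint, jointly covering all input wires) and
#' output existence.
#'
#' @param circ a circuit builder
#' @return an `mpc_circuit`: list with `kind`, `in1`, `in2`, `n_inputs`,
#'   `n_gates`, `n_wires`, `inputs_a`, `inputs_b`, `outputs`
#' @export
circuit_finalize <- function(circ) {
  ng <- circ$n_gates
  kind <- circ$kind[seq_len(ng)]
  in1 <- circ$in1[seq_len(ng)]
  in2 <- circ$in2[seq_len(ng)]
  ni <- circ$n_inputs
  out_wire <- ni + seq_len(ng)
  binop <- kind == GATE_AND | kind == GATE_XOR
  notop <- kind == GATE_NOT
  if (any(in1[binop | notop] < 1 | in1[binop | notop] >= out_wire[binop | notop]))
    stop("circuit is not topologically ordered: a gate reads a later wire")
  if (any(in2[binop] < 1 | in2[binop] >= out_wire[binop]))
    stop("circuit is not topologically ordered: a gate reads a later wire")
  if (any(!(circ$kind[seq_len(ng)][kind == GATE_CONST] == GATE_CONST &
            in1[kind == GATE_CONST] %in% c(0L, 1L))))
    stop("CONST gate with non-binary value")
  manifests <- c(circ$inputs_a, circ$inputs_b)
  if (anyDuplicated(manifests) || !setequal(manifests, seq_len(ni)))
    stop("party input manifests must partition wires 1..", ni)
  for (o in circ$outputs) {
    if (any(o$wires < 1 | o$wires > circ$n_wires))
      stop("output '", o$name, "' references a nonexistent wire")
    if (anyDuplicated(o$wires))
      stop("output '", o$name, "' repeats a wire")
  }
  structure(list(kind = kind, in1 = in1, in2 = in2,
                 n_inputs = ni, n_gates = ng, n_wires = circ$n_wires,
                 inputs_a = circ$inputs_a, inputs_b = circ$inputs_b,
                 outputs = circ$outputs),
            class = "mpc_circuit")
}

#' @export
print.mpc_circuit <- function(x, ...) {
  tab <- table(factor(GATE_NAMES[x$kind], levels = GATE_NAMES))
  cat("mpc_circuit:", x$n_gates, "gates,", x$n_inputs, "input wires (",
      length(x$inputs_a), "A /", length(x$inputs_b), "B ),",
      length(x$outputs), "output words\n")
  cat("  ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Plain (cleartext) circuit evaluation
#'
#' The reference evaluator: deterministic gate-by-gate evaluation used as
#' the correctness oracle for the garbled protocol.
#'
#' @param circ an `mpc_circuit`
#' @param bits_a,bits_b 0/1 integer vectors for the two parties' input
#'   wires, in manifest order
#' @return named numeric vector of decoded output words (exact while below
#'   2^53); the raw bits are attached as attribute `"bits"`
#' @export
evaluate_plain <- function(circ, bits_a, bits_b) {
  if (length(bits_a) != length(circ$inputs_a))
    stop("party A supplies ", length(bits_a), " bits but the circuit expects ",
         length(circ$inputs_a))
  if (length(bits_b) != length(circ$inputs_b))
    stop("party B supplies ", length(bits_b), " bits but the circuit expects ",
         length(circ$inputs_b))
  input_bits <- integer(circ$n_inputs)
  input_bits[circ$inputs_a] <- as.integer(bits_a)
  input_bits[circ$inputs_b] <- as.integer(bits_b)
  vals <- .eval_plain_cpp(circ$kind, circ$in1, circ$in2, circ$n_inputs,
                          input_bits)
  decode_output_bits(circ, function(wires) vals[wires])
}

# Shared output decoding for the plain and garbled paths: `bit_fn(wires)`
# returns the 0/1 values of the requested wires.
decode_output_bits <- function(circ, bit_fn) {
  values <- numeric(length(circ$outputs))
  names(values) <- vapply(circ$outputs, `[[`, character(1), "name")
  bits <- vector("list", length(circ$outputs))
  names(bits) <- names(values)
  for (i in seq_along(circ$outputs)) {
    o <- circ$outputs[[i]]
    b <- bit_fn(o$wires)
    bits[[i]] <- b
    values[i] <- bits_to_num(b)
  }
  structure(values, bits = bits,
            scales = vapply(circ$outputs, `[[`, integer(1), "scale"))
}

#' Concatenate independent copies of a template circuit
#'
#' Per-genotype statistic circuits have no cross-genotype wires, so a block
#' circuit is `k` disjoint copies of a one-genotype template.  Input wires
#' of all copies come first (copy-major order, matching packed-block word
#' order); outputs are renamed `"<name>/<i>"` with `i` the 1-based
#' within-block genotype index.
#'
#' @param template a finalized one-unit `mpc_circuit`
#' @param k number of copies
#' @return an `mpc_circuit` with `k * template$n_gates` gates
#' @export
replicate_circuit <- function(template, k) {
  stopifnot(k >= 1)
  ni <- template$n_inputs
  ng <- template$n_gates
  copy_idx <- rep(seq_len(k) - 1L, each = ng)
  map_wire <- function(v, copy0) {
    ifelse(v <= ni & v >= 1L, v + copy0 * ni, k * ni + copy0 * ng + (v - ni))
  }
  kind <- rep(template$kind, k)
  in1 <- rep(template$in1, k)
  in2 <- rep(template$in2, k)
  is_const <- kind == GATE_CONST
  is_bin <- kind == GATE_AND | kind == GATE_XOR
  in1[!is_const] <- map_wire(in1[!is_const], copy_idx[!is_const])
  in2[is_bin] <- map_wire(in2[is_bin], copy_idx[is_bin])
  outputs <- vector("list", k * length(template$outputs))
  oi <- 0L
  for (copy0 in 0:(k - 1L)) {
    for (o in template$outputs) {
      oi <- oi + 1L
      outputs[[oi]] <- list(name = paste0(o$name, "/", copy0 + 1L),
                            wires = as.integer(map_wire(o$wires, copy0)),
                            scale = o$scale)
    }
  }
  offs_a <- outer(template$inputs_a, (seq_len(k) - 1L) * ni, `+`)
  offs_b <- outer(template$inputs_b, (seq_len(k) - 1L) * ni, `+`)
  structure(list(kind = kind, in1 = as.integer(in1), in2 = as.integer(in2),
                 n_inputs = k * ni, n_gates = k * ng,
                 n_wires = k * template$n_wires,
                 inputs_a = as.integer(offs_a), inputs_b = as.integer(offs_b),
                 outputs = outputs),
            class = "mpc_circuit")
}

#' Serialize a circuit to a line-oriented text format
#'
#' One gate per line (`kind in1 in2`, the output wire being implicit), with
#' header lines for the input manifests and tagged outputs, so protocol
#' transcripts and golden circuits are diffable.
#'
#' @param circ an `mpc_circuit`
#' @param file output path or connection
#' @return `file` (write) or an `mpc_circuit` (read)
#' @export
write_circuit <- function(circ, file) {
  con <- if (inherits(file, "connection")) file else base::file(file, "w")
  if (!inherits(file, "connection")) on.exit(close(con))
  writeLines(c(
    "gwasmpc-circuit 1",
    paste("inputs", circ$n_inputs),
    paste("input_a", paste(circ$inputs_a, collapse = " ")),
    paste("input_b", paste(circ$inputs_b, collapse = " ")),
    vapply(circ$outputs, function(o) {
      paste("output", o$name, o$scale, paste(o$wires, collapse = " "))
    }, character(1)),
    paste("gates", circ$n_gates),
    sprintf("%s %d %d", GATE_NAMES[circ$kind], circ$in1, circ$in2)
  ), con)
  invisible(file)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(file) {
  lines <- readLines(file)
  if (lines[1] != "gwasmpc-circuit 1") stop("not a gwasmpc circuit file")
  ni <- as.integer(strsplit(lines[2], " ")[[1]][2])
  parse_ids <- function(line) {
    parts <- strsplit(line, " ")[[1]][-1]
    as.integer(parts[nzchar(parts)])
  }
  inputs_a <- parse_ids(lines[3])
  inputs_b <- parse_ids(lines[4])
  i <- 5L
  outputs <- list()
  while (startsWith(lines[i], "output ")) {
    parts <- strsplit(lines[i], " ")[[1]]
    outputs[[length(outputs) + 1L]] <-
      list(name = parts[2], wires = as.integer(parts[-(1:3)]),
           scale = as.integer(parts[3]))
    i <- i + 1L
  }
  ng <- as.integer(strsplit(lines[i], " ")[[1]][2])
  gl <- lines[i + seq_len(ng)]
  parts <- strsplit(gl, " ", fixed = TRUE)
  kind <- match(vapply(parts, `[[`, character(1), 1), GATE_NAMES)
  in1 <- as.integer(vapply(parts, `[[`, character(1), 2))
  in2 <- as.integer(vapply(parts, `[[`, character(1), 3))
  structure(list(kind = as.integer(kind), in1 = in1, in2 = in2,
                 n_inputs = ni, n_gates = ng, n_wires = ni + ng,
                 inputs_a = inputs_a, inputs_b = inputs_b, outputs = outputs),
            class = "mpc_circuit")
}
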