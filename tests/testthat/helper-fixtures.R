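# Shared fixtures: all inputs are built in code, no stored data.

# The five-individual worked example (genotypes AA, AG, AA, AG, GG at one
# locus) split 3/2 across the two institutions, with the same individuals
# duplicated as case and control groups.
worked_example_parties <- function(locus = "rs11686243") {
  party_of <- function(calls) {
    recs <- parse_snp_file(c(locus, paste(calls, collapse = " ")))
    case <- count_alleles(recs, "case")
    control <- count_alleles(recs, "control")
    list(case = case, control = control,
         meta = build_metadata(case, control))
  }
  list(a = party_of(c("AA", "AG", "AA")),
       b = party_of(c("AG", "GG")))
}

# Build an allele_counts object directly from low/high allele counts.
counts_from_lows <- function(loci, low, n_individuals,
                             low_allele = "A", high_allele = "G",
                             group = "case") {
  stopifnot(length(low) == length(loci), all(low <= 2 * n_individuals))
  m <- matrix(0L, nrow = length(loci), ncol = 4,
              dimnames = list(loci, c("A", "C", "G", "T")))
  m[, low_allele] <- as.integer(low)
  m[, high_allele] <- as.integer(2L * n_individuals - low)
  structure(m, loci = loci, group = group,
            n_individuals = as.integer(n_individuals),
            class = c("allele_counts", "matrix"))
}

# Metadata for a biallelic (A/G) study with the given per-group individual
# counts (totals are allele copies = 2x individuals).
test_meta <- function(n_loci = 1, n_case = 10, n_control = 10) {
  gwasmpc:::new_study_metadata(sprintf("rs%04d", seq_len(n_loci)),
                               rep("A", n_loci), rep("G", n_loci),
                               n_case, n_control)
}

# One genotype's 32 circuit input bits from its (case_low, control_low)
# counts: control field in the low-order 16 bits, case in the high-order.
word_bits <- function(case_low, control_low) {
  c(gwasmpc:::int_to_bits(control_low, 16),
    gwasmpc:::int_to_bits(case_low, 16))
}

# Input bit vectors for a block circuit from count matrices (rows =
# genotypes, cols = case_low / control_low).
block_bits <- function(counts) {
  unlist(lapply(seq_len(nrow(counts)), function(i) {
    word_bits(counts[i, 1], counts[i, 2])
  }))
}

# A random (but valid) circuit for garbled-vs-plain equivalence testing:
# gates draw inputs uniformly from already-defined wires.
random_circuit <- function(n_inputs_a = 4, n_inputs_b = 4, n_gates = 50) {
  circ <- circuit_new()
  a <- circuit_inputs(circ, "A", n_inputs_a)
  b <- circuit_inputs(circ, "B", n_inputs_b)
  kinds <- sample(c(gwasmpc:::GATE_AND, gwasmpc:::GATE_XOR,
                    gwasmpc:::GATE_NOT, gwasmpc:::GATE_CONST),
                  n_gates, replace = TRUE, prob = c(0.4, 0.4, 0.15, 0.05))
  for (k in kinds) {
    avail <- gwasmpc:::peek_wire(circ)
    if (k == gwasmpc:::GATE_CONST) {
      gwasmpc:::emit(circ, k, sample(0:1, 1))
    } else if (k == gwasmpc:::GATE_NOT) {
      gwasmpc:::emit(circ, k, sample.int(avail, 1))
    } else {
      gwasmpc:::emit(circ, k, sample.int(avail, 1), sample.int(avail, 1))
    }
  }
  n_out <- min(8L, n_gates)
  out_wires <- gwasmpc:::peek_wire(circ) - seq_len(n_out) + 1L
  mark_output(circ, "out", sort(out_wires))
  circuit_finalize(circ)
}

rand_bits <- function(n) sample(0:1, n, replace = TRUE)
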