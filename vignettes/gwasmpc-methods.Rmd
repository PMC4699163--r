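---
title: "Secure two-party GWAS statistics: model, circuits, and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure two-party GWAS statistics: model, circuits, and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasmpc)
```

## The problem

Two institutions each hold case/control SNP genotypes for their own
patients.  Pooling the raw genotypes would give a better-powered
association study, but raw genomic data is identifying and cannot cross
institutional boundaries.  `gwasmpc` lets the two parties compute, per
locus, the pooled minor allele frequency (MAF) and the 2×2 allelic
chi-squared association statistic, revealing to each other only agreed
public metadata — locus list, allele pairs, group sizes — and the final
statistics.  The cryptographic engine is the classic Yao garbled-circuit
protocol for secure two-party computation in the semi-honest
(honest-but-curious) model, with 1-out-of-2 oblivious transfer delivering
the evaluator's inputs.

## Statistical model

At a biallelic locus with alleles ordered lexicographically (low < high),
write `lowCt_g` for the pooled count of low-allele copies in group
`g ∈ {case, control}` and `TOTAL_g = 2 n_g` for the group's allele copies
(`n_g` individuals, two copies each).  Then

* **MAF**: `minCt_g = min(lowCt_g, TOTAL_g − lowCt_g)` and
  `MAF_g = minCt_g / TOTAL_g`, always in `[0, 0.5]`.
* **Chi-squared**: over the 2×2 group-by-allele table with observed counts
  `obs = (case-low, case-high, control-low, control-high)`, expected
  counts `exp_ij = row_i · col_j / N` (`N` the grand total), the statistic
  is `χ² = Σ_ij (obs_ij − exp_ij)² / exp_ij`.  No continuity correction is
  applied, and no p-values are produced — the raw statistic is the
  protocol's output.

Only the initial allele counting is local.  Everything downstream of the
counts mixes both parties' private data (even the expected counts depend
on both parties' marginals), so it runs inside the secure computation.

## Fixed-point arithmetic

Boolean circuits here carry unsigned integers only.  Division is realised
at a fixed-point precision of `FPP` fractional bits (default 16): a
quotient `a / b` is computed as `floor(a · 2^FPP / b)`, so every reported
mantissa `m` decodes to `m / 2^16`.  Because `2^−16` has a finite decimal
expansion, `decode_fixed_point()` renders mantissas exactly and
`parse_fixed_point()` recovers them losslessly.

Subtraction is the dangerous operation: an unsigned `(obs − exp)²` could
underflow when `obs < exp`.  The circuit therefore expands

```
(obs − exp)² = obs² + exp² − 2·obs·exp
```

and performs the single subtraction `obs² + exp² − 2·obs·exp`, which is
non-negative by the AM–GM inequality; the borrow wire of that subtraction
is exposed in debug builds and property-tested to be zero.  Products are
kept at full width (widths grow as needed; a cell's numerator occupies
`2·(t + FPP) + 1` bits for group totals of `t` bits), and each cell takes
exactly one floor division, minimising truncation.

**Accuracy.** The only error sources are the flooring of `exp` at scale
`2^−FPP` and the final per-cell floor.  Propagating the quantisation
through `t(e) = obs²/e − 2·obs + e` bounds the per-cell error by
`2^−FPP · (obs² / (e · e_fp) + 2)`, with `e_fp` the decoded fixed-point
expectation.  The test suite verifies this bound empirically on random
tables with totals up to 800, and checks the closed-form table
case (10,0) / control (0,10), whose statistic is exactly 20, to within
`4·2^−12`.

## Input packing

Private counts travel as hexadecimal blocks of at most 8,000 bits, the
input ceiling of the runtime this layout targets.  One genotype consumes
one 32-bit word — case-group low-allele count in the high 16 bits,
control-group count in the low 16 — so a block holds up to 250 genotypes
and a study of `m` genotypes needs `ceil(m / 250)` blocks (9,330 genotypes
→ 38 blocks).  Only the low-allele count is transmitted; the high count is
reconstructed in-circuit as `TOTAL − low`, halving input size.  The
16-bit field caps a pooled group at 65,535 allele copies (32,767
individuals); the bound is enforced at pack time rather than assumed.
Word order is fixed (first genotype leftmost, big-endian within a word)
and locked by round-trip tests; the original layout never specified an
endianness, so one convention is chosen and documented.

Missing or ambiguous calls (`NN`, `00`, `--`) are rejected outright rather
than dropped: the circuit bakes `TOTAL` in as a compile-time constant, so
a silently dropped individual would corrupt every downstream count.
Monomorphic loci are completed with a zero-count sentinel allele (keeping
the block layout uniform; their MAF is 0 and their chi-squared 0 with a
degeneracy flag).  Loci with more than two observed alleles are a hard
error — the circuits are strictly biallelic.

## Circuits

`circuit_core` provides the gate basis {AND, XOR, NOT, CONST} (OR is
desugared) and unsigned word primitives: ripple-carry addition, borrow
subtraction with the borrow exposed, shift-and-add multiplication,
restoring division (bit-exact floor semantics — Newton/SRT variants would
not give the exact floors the oracle tests freeze), comparison,
multiplexing, and constant embedding.  Division by zero is total rather
than faulting (circuits cannot branch): it yields an all-ones quotient,
and is unreachable from the statistic circuits because denominators are
public totals or zero-gated expectations.

Widths are sized from the *public* totals: with 400 allele copies per
group a chi-squared genotype costs ~120k gates, dominated by the four
per-cell multiply/divide stages; MAF genotypes cost ~8k.  Per-genotype
circuits are independent (no cross-genotype wires), so a block circuit is
a replicated template — which both preserves the genotype-independence
that justifies parallel blocks and makes construction cheap.

Two deliberate degeneracy policies: a pooled-monomorphic column would
divide by zero, so those cells are gated to zero and a one-bit `deg`
output flags the genotype (a monomorphic site carries no association
signal; 0 is the statistically meaningful report, in preference to the
divide-by-zero sentinel word).  A MAF tie (`lowCt = highCt`) takes the
low branch of a strict comparator — both branches are the same value, so
the choice is unbiased.

## Protocol

Garbling uses classic four-row tables with point-and-permute: each wire
gets two 128-bit labels with complementary permute flags; each AND/XOR
row is encrypted under `SHA256(label_a ‖ label_b ‖ gate id)` with 16
bytes masking the output label and 8 bytes authenticating the row, so a
corrupted circuit fails loudly instead of decoding garbage.  NOT gates
swap the label pair and cost nothing; free-XOR, half-gates and row
reduction are deliberately absent — correctness and auditability first.

The evaluator's input labels travel by Naor–Pinkas style semi-honest
1-out-of-2 OT, one transfer per input bit, implemented over the
multiplicative group modulo the Mersenne prime `2^521 − 1` (the Mersenne
form keeps modular reduction to a fold; the field is well-studied and
the protocol structure is standard).  OT extension is out of scope.

The original description is ambiguous about who decodes the output; this
implementation fixes the convention: the evaluator returns output
*labels*, the generator (who holds the label→bit maps) decodes and sends
the plaintext statistics back, so both institutions end with the results.

All protocol randomness comes from a seedable SHA-256 counter-mode PRG.
Seeded runs are byte-reproducible — transcripts are regression-testable —
and carry an explicit warning in the documentation: a known seed makes
every label predictable.  Unseeded (production) runs draw from OS
entropy.

**Leakage.** By design both parties learn: locus list and order, allele
pairs, group sizes, genotype count, circuit shape, and transcript sizes.
The tests assert the transcript's structure depends only on these public
quantities, never on the private counts.  An institution unwilling to
reveal even its genotype count can pad all computations to a public upper
bound (`padded_block_plan()`); padding genotypes are zero-count
placeholders whose outputs are discarded.

## Transports and parallelism

Sessions run either over an in-process loopback (simulate mode — both
roles in one process, every protocol message still constructed and
measured) or over length-prefixed frames on TCP with generator and
evaluator roles.  Blocks are independent sessions; in simulate mode up to
`workers` run concurrently via forked processes, with a per-block seed
derived from the master seed so merged results are identical for any
worker count.  Networked runs process blocks sequentially over the single
connection — parallel TCP port-per-block sessions were judged not worth
the operational fragility, and the parallelism contract (independent
sessions, order-preserving merge, failure names the block) is exercised
in simulate mode.

## Synthetic data

`generate_synthetic_study()` emulates the data shape the protocol
consumes: two institutions × case/control SNP text files over a shared
locus list, with each individual's two allele copies drawn i.i.d. from
the group allele frequency (Hardy–Weinberg sampling).  Defaults mirror a
four-way 100/100/100/100 split of 200 case and 200 control individuals
over 311 loci, with per-locus minor-allele frequencies uniform on
[0.05, 0.5], 10% of loci "associated", and an additive case-frequency
shift of 0.15 at associated loci — a moderate, detectable effect at these
sample sizes.  A ground-truth TSV records the simulated frequencies and
exact pooled counts for end-to-end verification.

Deliberately not modelled: linkage disequilibrium, population
stratification, genotyping error, missingness.  Passing tests therefore
demonstrate protocol and arithmetic correctness on realistic *counts*,
not robustness to real-cohort artefacts — the statistic computed on real
data is exactly the cleartext statistic of the pooled counts, so those
artefacts affect interpretation, not correctness.

## Test scale choices

The suite verifies primitives exhaustively at small widths and randomly
at full widths; garbled-vs-plain equivalence on 200 random circuits and
on full block circuits over 1,000 random count tables per statistic
(garbling once per block — tables are input-independent); and an
end-to-end synthetic study at 50 loci with 100/100/100/100 individuals,
split into four blocks so the worker-count invariance is meaningful.
These sizes keep the whole suite in a few minutes on one core while
exercising every code path at the study's count magnitudes.

## Known limitations

* Two parties only; the garbled-circuit runtime is inherently two-party.
* Semi-honest security only: no cut-and-choose or other malicious-model
  hardening, and the OT is semi-honest.
* No garbling optimisations (free-XOR, half-gates): transcripts are
  several times larger than an optimised implementation's.
* Statistics are the raw MAF and chi-squared values: no p-values,
  genomic control, or multiple-testing correction.
* Input is the plain-text SNP dialect only (no VCF/PLINK), with no
  quality filtering, HWE checks, or imputation.
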