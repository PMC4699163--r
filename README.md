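# gwasmpc

Privacy-preserving two-party GWAS statistics via Yao garbled circuits.

Two institutions each hold case/control SNP genotype files they are not
allowed to share.  `gwasmpc` lets them jointly compute, per locus, the
**pooled minor allele frequency (MAF)** and the **2×2 allelic χ²
association statistic** over the combined cohort, without either party
revealing its per-locus allele counts.  The cryptography is the classic
Yao garbled-circuit protocol in the semi-honest model, with Naor–Pinkas
style 1-out-of-2 oblivious transfer delivering the evaluator's inputs.

## The statistics

At a biallelic locus, with `lowCt_g` the pooled copies of the
lexicographically lower allele in group *g* and `TOTAL_g = 2·n_g` the
group's allele copies:

* MAF: `min(lowCt_g, TOTAL_g − lowCt_g) / TOTAL_g`
* χ²: `Σ_ij (obs_ij − exp_ij)² / exp_ij` over the 2×2 group × allele
  table, with `exp_ij = row_i · col_j / N`

All in-circuit arithmetic is unsigned fixed point with `FPP = 16`
fractional bits (`a/b` is `floor(a·2¹⁶/b)`); the χ² numerator is expanded
as `obs² + exp² − 2·obs·exp` so no subtraction can go negative.  Only the
initial allele counting is local: everything past the counts mixes both
parties' private data and runs inside the garbled circuit.

Private counts are bit-packed into hexadecimal blocks of at most 8,000
bits — 32 bits per genotype (16-bit case and control counts of the low
allele), so 250 genotypes per block and `ceil(m/250)` blocks for *m*
genotypes (9,330 genotypes → 38 blocks).

## Worked example

Five individuals at one locus with genotypes `AA AG AA AG GG` — the
G allele occurs 4 times in 10 copies, so the MAF is 0.4.  Split the
individuals across two institutions and run the full secure pipeline in
simulate mode (both roles in one process, every protocol message still
exchanged and measured):

```r
library(gwasmpc)

party_of <- function(calls) {
  recs <- parse_snp_file(c("rs11686243", paste(calls, collapse = " ")))
  case    <- count_alleles(recs, "case")
  control <- count_alleles(recs, "control")
  list(case = case, control = control, meta = build_metadata(case, control))
}
party_a <- party_of(c("AA", "AG", "AA"))   # institution 1: 3 individuals
party_b <- party_of(c("AG", "GG"))         # institution 2: 2 individuals

run <- mpc_run_study(party_a, party_b, "maf", seed = 1)
run$results
#>        locus   statistic mantissa             value degenerate
#> 1 rs11686243    maf_case    26214 0.399993896484375      FALSE
#> 2 rs11686243 maf_control    26214 0.399993896484375      FALSE
```

The mantissa 26214 is `floor(4·2¹⁶/10)`, the fixed-point image of 4/10;
it decodes to 0.39999… and rounds to the expected 0.4.  The same runner
computes χ² (`statistic = "chi2"`); on the disjoint table case (10,0)
vs control (0,10) it reports 20.0 to within the fixed-point bound.

A synthetic two-party study generator (`generate_synthetic_study()`),
cleartext fixed-point oracles (`cleartext_maf()`, `cleartext_chi2()`) and
a floating-point reference (`float_chi2()`) make the whole pipeline
verifiable end to end; `inst/cli/gwasmpc` wraps preprocess / run /
decode / synth as shell subcommands, including real networked
generator/evaluator roles over TCP.

## Scope

Semi-honest security, two parties, raw statistics only (no p-values or
multiple-testing correction), plain-text SNP input dialect.  See the
methods vignette (`vignettes/gwasmpc-methods.Rmd`) for the model,
fixed-point error analysis, leakage surface, and design rationale.
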