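Package: gwasmpc
Title: Privacy-Preserving Two-Party GWAS via Yao Garbled Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two institutions jointly compute minor allele frequencies and
    chi-squared association statistics over pooled case/control SNP data
    without revealing per-locus allele counts to each other.  The package
    parses a plain-text SNP dialect (rsID line followed by whitespace
    separated diploid calls), counts alleles locally, bit-packs the private
    counts into bounded hexadecimal input blocks, compiles the statistics
    into unsigned fixed-point boolean circuits, and evaluates them under the
    Yao garbled-circuit protocol with 1-out-of-2 oblivious transfer in the
    semi-honest model.  Cleartext fixed-point oracles, a floating-point
    chi-squared reference, and a synthetic two-party case/control study
    generator make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
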