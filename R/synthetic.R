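# Synthetic two-party case/control study generator.  Emulates the data
# shape the protocol consumes -- two institutions, each with a case and a
# control SNP text file over a shared locus list -- with Hardy-Weinberg
# sampling: each individual's two allele copies are drawn i.i.d. from the
# group's allele frequency.  Real cohort features deliberately not modelled:
# linkage disequilibrium, population stratification, genotyping error.

#' Describe a synthetic two-party case/control study
#'
#' @param n_case,n_control individuals per group *per party* (default
#'   100/100, i.e. the classic 100+100 case and 100+100 control split)
#' @param n_loci number of genotypes (default 311)
#' @param maf_range range the per-locus population minor-allele frequency
#'   is drawn uniformly from (within `[0, 0.5]`)
#' @param assoc_fraction fraction of loci given a case/control frequency
#'   shift (the "associated" loci)
#' @param effect_shift additive shift applied to the case-group allele
#'   frequency at associated loci (clamped to `[0, 1]`)
#' @param seed integer seed; fully determines the generated files
#' @return a `synthetic_study_spec`
#' @export
synthetic_study_spec <- function(n_case = 100, n_control = 100, n_loci = 311,
                                 maf_range = c(0.05, 0.5),
                                 assoc_fraction = 0.1, effect_shift = 0.15,
                                 seed = 1) {
  stopifnot(n_case >= 1, n_control >= 1, n_loci >= 1,
            maf_range[1] >= 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            assoc_fraction >= 0, assoc_fraction <= 1)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_loci = as.integer(n_loci),
                 maf_range = as.numeric(maf_range),
                 assoc_fraction = as.numeric(assoc_fraction),
                 effect_shift = as.numeric(effect_shift),
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a synthetic two-party study
#'
#' Writes four SNP text files (party x group) in the dialect consumed by
#' [parse_snp_file()] plus a tab-separated ground-truth table recording the
#' simulated group frequencies and the exact pooled counts, enabling
#' end-to-end verification of the secure pipeline against known truth.
#'
#' @param spec a [synthetic_study_spec()]
#' @param dir output directory (created if needed)
#' @return list with `files` (named paths: `a_case`, `a_control`, `b_case`,
#'   `b_control`), `truth_file`, and `truth` (data.frame)
#' @export
generate_synthetic_study <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n_loci <- spec$n_loci
  loci <- sprintf("rs%06d", seq_len(n_loci))
  pop_maf <- runif(n_loci, spec$maf_range[1], spec$maf_range[2])
  associated <- runif(n_loci) < spec$assoc_fraction
  f_control <- pop_maf
  f_case <- pmin(pmax(pop_maf + ifelse(associated, spec$effect_shift, 0), 0), 1)
  pair <- t(vapply(seq_len(n_loci), function(i) {
    sort(sample(NUCLEOTIDES, 2))
  }, character(2)))
  ref <- pair[, 1]
  alt <- pair[, 2]   # the allele carrying frequency f_group

  draw_group <- function(n_ind, freq) {
    # 2 i.i.d. copies per individual; returns calls and the alt-copy count
    copies <- matrix(rbinom(2 * n_ind * n_loci, 1, rep(freq, each = 2 * n_ind)),
                     nrow = 2 * n_ind)
    list(copies = copies, alt_copies = colSums(copies))
  }
  calls_of <- function(copies, i) {
    a1 <- ifelse(copies[seq(1, nrow(copies), 2), i] == 1, alt[i], ref[i])
    a2 <- ifelse(copies[seq(2, nrow(copies), 2), i] == 1, alt[i], ref[i])
    paste0(a1, a2)
  }
  make_records <- function(draw) {
    lapply(seq_len(n_loci), function(i) {
      list(locus_id = loci[i], calls = calls_of(draw$copies, i))
    })
  }

  parts <- list(
    a_case = draw_group(spec$n_case, f_case),
    b_case = draw_group(spec$n_case, f_case),
    a_control = draw_group(spec$n_control, f_control),
    b_control = draw_group(spec$n_control, f_control)
  )
  files <- c(a_case = file.path(dir, "party_a_case.snp"),
             a_control = file.path(dir, "party_a_control.snp"),
             b_case = file.path(dir, "party_b_case.snp"),
             b_control = file.path(dir, "party_b_control.snp"))
  for (nm in names(files)) {
    write_snp_file(make_records(parts[[nm]]), files[[nm]])
  }

  truth <- data.frame(
    locus = loci, allele_ref = ref, allele_alt = alt,
    f_case = f_case, f_control = f_control, associated = associated,
    case_alt_copies = parts$a_case$alt_copies + parts$b_case$alt_copies,
    control_alt_copies = parts$a_control$alt_copies +
      parts$b_control$alt_copies,
    case_total = 2L * 2L * spec$n_case,
    control_total = 2L * 2L * spec$n_control,
    stringsAsFactors = FALSE
  )
  truth_file <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(files = files, truth_file = truth_file, truth = truth)
}
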