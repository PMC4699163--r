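# Parsing the plain-text SNP dialect, local allele counting, and the public
# study metadata both institutions must agree on before any joint computation.
#
# File dialect: pairs of lines, the first a locus identifier (e.g. an rsID),
# the second whitespace-separated two-character diploid calls over {A,C,G,T}:
#
#   rs11686243
#   AG AG AA AG GG
#
# Any whitespace (spaces, tabs, wrapped lines are NOT supported -- one call
# line per locus) separates calls.

#' Parse a SNP text file
#'
#' Reads alternating locus-ID / genotype-call lines.  Every call must be a
#' two-character string over `{A,C,G,T}` and every locus must list the same
#' number of individuals.  Missing or ambiguous calls (`NN`, `00`, `--`) are
#' rejected: downstream circuits bake the exact group total in as a public
#' constant, so individuals cannot be dropped locus-wise.
#'
#' @param file path to a SNP text file, a connection, or a character vector
#'   of lines (useful for tests).
#' @return an object of class `snp_records`: a list with one element per
#'   locus, each a list with `locus_id` and `calls` (character vector).
#' @examples
#' recs <- parse_snp_file(c("rs11686243", "AG AG AA AG GG"))
#' length(recs[[1]]$calls)  # 5 individuals
#' @export
parse_snp_file <- function(file) {
  lines <- if (is.character(file) && length(file) != 1) {
    file
  } else if (is.character(file) && !file.exists(file) && grepl("\n", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(file)
  }
  # drop trailing blank lines only; interior blanks are structural errors
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0) {
    return(structure(list(), class = "snp_records"))
  }
  if (length(lines) %% 2 != 0) {
    stop("SNP file is truncated: locus ID on line ", length(lines),
         " has no genotype line")
  }
  id_lines <- lines[seq(1, length(lines), by = 2)]
  call_lines <- lines[seq(2, length(lines), by = 2)]
  ids <- trimws(id_lines)
  if (any(!nzchar(ids))) {
    bad <- 2 * which(!nzchar(ids))[1] - 1
    stop("empty locus ID on line ", bad)
  }
  records <- vector("list", length(ids))
  n_ind <- NA_integer_
  for (i in seq_along(ids)) {
    lineno <- 2L * i
    calls <- strsplit(trimws(call_lines[i]), "[[:space:]]+")[[1]]
    calls <- calls[nzchar(calls)]
    if (length(calls) == 0) {
      stop("no genotype calls on line ", lineno, " (locus ", ids[i], ")")
    }
    bad_len <- which(nchar(calls) != 2)
    if (length(bad_len) > 0) {
      stop("malformed call '", calls[bad_len[1]], "' on line ", lineno,
           ", column ", bad_len[1], ": calls must be two characters")
    }
    chars <- strsplit(paste0(calls, collapse = ""), "")[[1]]
    bad_char <- which(!chars %in% NUCLEOTIDES)
    if (length(bad_char) > 0) {
      col <- ceiling(bad_char[1] / 2)
      stop("invalid nucleotide '", chars[bad_char[1]], "' on line ", lineno,
           ", column ", col, " (locus ", ids[i],
           "): alleles must be A, C, G or T")
    }
    if (is.na(n_ind)) {
      n_ind <- length(calls)
    } else if (length(calls) != n_ind) {
      stop("inconsistent individual count: locus ", ids[i], " (line ",
           lineno, ") has ", length(calls), " calls but earlier loci have ",
           n_ind)
    }
    records[[i]] <- list(locus_id = ids[i], calls = calls)
  }
  structure(records, class = "snp_records")
}

#' Write SNP records in the text dialect
#' @param records an `snp_records` object or a list of
#'   `list(locus_id, calls)` entries
#' @param file output path or connection
#' @return `file`, invisibly
#' @export
write_snp_file <- function(records, file) {
  lines <- unlist(lapply(records, function(r) {
    c(r$locus_id, paste(r$calls, collapse = " "))
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Count alleles per locus for one group
#'
#' A pure fold over the call characters; this is the only computation each
#' institution performs on its raw genotypes, and it stays local -- the
#' resulting counts are the private inputs to the joint protocol.
#'
#' @param records an `snp_records` object from [parse_snp_file()]
#' @param group `"case"` or `"control"`
#' @return an `allele_counts` object: integer matrix (loci x `A,C,G,T`) with
#'   attributes `loci`, `group` and `n_individuals`.
#' @examples
#' recs <- parse_snp_file(c("rs1", "AA AG AA AG GG"))
#' count_alleles(recs, "case")  # A: 6, G: 4
#' @export
count_alleles <- function(records, group = c("case", "control")) {
  group <- match.arg(group)
  if (length(records) == 0) {
    m <- matrix(0L, nrow = 0, ncol = 4, dimnames = list(NULL, NUCLEOTIDES))
    return(structure(m, loci = character(0), group = group,
                     n_individuals = 0L, class = "allele_counts"))
  }
  counts <- t(vapply(records, function(r) {
    chars <- strsplit(paste0(r$calls, collapse = ""), "")[[1]]
    tabulate(factor(chars, levels = NUCLEOTIDES), nbins = 4)
  }, integer(4)))
  colnames(counts) <- NUCLEOTIDES
  loci <- vapply(records, `[[`, character(1), "locus_id")
  rownames(counts) <- loci
  n_ind <- length(records[[1]]$calls)
  stopifnot(all(rowSums(counts) == 2L * n_ind))  # allele-copy conservation
  structure(counts, loci = loci, group = group, n_individuals = n_ind,
            class = c("allele_counts", "matrix"))
}

#' Build one institution's public study metadata
#'
#' Derives, from the local case and control counts, everything that will be
#' treated as public: the ordered locus list, the observed allele pair per
#' locus (ordered lexicographically), and the group sizes.  Only the counts
#' themselves stay private.
#'
#' Monomorphic loci (a single observed allele) are retained; their allele
#' pair is completed later with a zero-count sentinel so the packed block
#' layout stays uniform.  More than two observed alleles at a locus is a hard
#' error: the statistic circuits are strictly biallelic.
#'
#' @param case_counts,control_counts `allele_counts` for the two groups,
#'   over an identical ordered locus list
#' @return a `study_metadata` object
#' @export
build_metadata <- function(case_counts, control_counts) {
  loci <- attr(case_counts, "loci")
  if (!identical(loci, attr(control_counts, "loci"))) {
    stop("case and control counts cover different loci")
  }
  if (anyDuplicated(loci)) {
    stop("duplicate locus ID: ", loci[duplicated(loci)][1])
  }
  n_case <- attr(case_counts, "n_individuals")
  n_control <- attr(control_counts, "n_individuals")
  if (n_case == 0 || n_control == 0) {
    stop("both groups must contain at least one individual")
  }
  pooled <- unclass(case_counts) + unclass(control_counts)
  obs1 <- character(length(loci))
  obs2 <- rep(NA_character_, length(loci))
  for (i in seq_along(loci)) {
    present <- NUCLEOTIDES[pooled[i, ] > 0]
    if (length(present) > 2) {
      stop("locus ", loci[i], " has ", length(present),
           " alleles (", paste(present, collapse = ", "),
           "); only biallelic loci are supported")
    }
    obs1[i] <- present[1]
    if (length(present) == 2) obs2[i] <- present[2]
  }
  new_study_metadata(loci, obs1, obs2, n_case, n_control)
}

new_study_metadata <- function(loci, obs1, obs2, n_case, n_control) {
  structure(list(
    loci = data.frame(locus = loci, obs1 = obs1, obs2 = obs2,
                      stringsAsFactors = FALSE),
    n_case = as.integer(n_case),
    n_control = as.integer(n_control),
    total_case = 2L * as.integer(n_case),
    total_control = 2L * as.integer(n_control)
  ), class = "study_metadata")
}

#' @export
print.study_metadata <- function(x, ...) {
  cat("study_metadata:", nrow(x$loci), "loci;",
      x$n_case, "case /", x$n_control, "control individuals",
      "(", x$total_case, "/", x$total_control, "allele copies)\n")
  invisible(x)
}

#' Per-locus (low, high) allele pairs
#'
#' Completes monomorphic loci with a sentinel second allele (the first
#' nucleotide in A,C,G,T order different from the observed one) whose count
#' is necessarily zero, then orders each pair lexicographically.  The "low"
#' allele is the lexicographically lower one; its counts are what gets
#' transmitted, the high counts being reconstructed in-circuit as
#' `TOTAL - low`.
#'
#' @param meta a `study_metadata` object
#' @return data.frame with columns `locus`, `low`, `high`, `monomorphic`
#' @export
meta_pairs <- function(meta) {
  df <- meta$loci
  mono <- is.na(df$obs2)
  second <- df$obs2
  if (any(mono)) {
    second[mono] <- vapply(df$obs1[mono], function(a) {
      setdiff(NUCLEOTIDES, a)[1]
    }, character(1))
  }
  low <- pmin(df$obs1, second)
  high <- pmax(df$obs1, second)
  data.frame(locus = df$locus, low = low, high = high, monomorphic = mono,
             stringsAsFactors = FALSE)
}

#' Merge the two institutions' metadata
#'
#' The two parties exchange their (public) metadata in the clear and merge
#' it: the locus list becomes the intersection in the first argument's
#' order, allele observations are unioned per locus (an union of more than
#' two alleles is irreconcilable), and group totals are summed.  In a
#' session the generator's metadata is conventionally passed first so both
#' parties derive byte-identical merged metadata.
#'
#' @param meta_a,meta_b `study_metadata` from the two institutions
#' @return merged `study_metadata` (individual counts and totals are sums)
#' @export
reconcile_metadata <- function(meta_a, meta_b) {
  loci <- intersect(meta_a$loci$locus, meta_b$loci$locus)
  if (length(loci) == 0) {
    stop("the two parties share no loci; nothing to compute")
  }
  ia <- match(loci, meta_a$loci$locus)
  ib <- match(loci, meta_b$loci$locus)
  obs1 <- character(length(loci))
  obs2 <- rep(NA_character_, length(loci))
  for (i in seq_along(loci)) {
    al <- unique(stats::na.omit(c(meta_a$loci$obs1[ia[i]],
                                  meta_a$loci$obs2[ia[i]],
                                  meta_b$loci$obs1[ib[i]],
                                  meta_b$loci$obs2[ib[i]])))
    al <- sort(al)
    if (length(al) > 2) {
      stop("irreconcilable locus ", loci[i], ": allele union {",
           paste(al, collapse = ", "), "} exceeds two alleles")
    }
    obs1[i] <- al[1]
    if (length(al) == 2) obs2[i] <- al[2]
  }
  new_study_metadata(loci, obs1, obs2,
                     meta_a$n_case + meta_b$n_case,
                     meta_a$n_control + meta_b$n_control)
}

#' Write / read study metadata as a JSON sidecar
#' @param meta a `study_metadata` object
#' @param file path to a JSON file
#' @return `file` (write) or a `study_metadata` (read)
#' @export
write_metadata <- function(meta, file) {
  obj <- list(
    format = "gwasmpc-metadata",
    version = 1L,
    n_case = meta$n_case,
    n_control = meta$n_control,
    loci = meta$loci
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, na = "null")
  invisible(file)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!identical(obj$format, "gwasmpc-metadata")) {
    stop("not a gwasmpc metadata file: ", file)
  }
  loci <- obj$loci
  obs2 <- loci$obs2
  if (is.null(obs2)) obs2 <- rep(NA_character_, nrow(loci))
  new_study_metadata(loci$locus, loci$obs1, as.character(obs2),
                     obj$n_case, obj$n_control)
}

#' Write / read per-locus allele counts as TSV
#' @param counts an `allele_counts` object
#' @param file path
#' @return `file` (write) or an `allele_counts` (read)
#' @export
write_counts <- function(counts, file) {
  df <- data.frame(locus = attr(counts, "loci"), unclass(counts)[, , drop = FALSE],
                   stringsAsFactors = FALSE)
  attr(df, "row.names") <- seq_len(nrow(df))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# group=", attr(counts, "group"),
                    " n_individuals=", attr(counts, "n_individuals")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_counts
#' @export
read_counts <- function(file) {
  header <- readLines(file, n = 1)
  m <- regmatches(header, regexec("# group=(\\w+) n_individuals=(\\d+)", header))[[1]]
  if (length(m) != 3) stop("not a gwasmpc counts file: ", file)
  df <- utils::read.table(file, sep = "\t", header = TRUE, skip = 1,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", rep("integer", 4)))
  mat <- as.matrix(df[, NUCLEOTIDES])
  rownames(mat) <- df$locus
  structure(mat, loci = df$locus, group = m[2],
            n_individuals = as.integer(m[3]),
            class = c("allele_counts", "matrix"))
}
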