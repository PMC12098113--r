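## MHC class-I presentation: pluggable percentile-rank predictors, the 5%
## binder threshold, and cohort aggregation statistics.

#' Parse HLA class-I allele names
#'
#' Accepts names of the form `HLA-A02:01`; returns the locus (A/B/C).
#'
#' @param alleles Character vector of allele names.
#' @return Character vector of loci.
#' @export
hla_locus <- function(alleles) {
  m <- regmatches(alleles, regexec("^HLA-([ABC])[0-9]+:[0-9]+$", alleles))
  loci <- vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
                 character(1))
  if (anyNA(loci)) {
    .stopf("unparseable HLA allele name(s): %s",
           paste(alleles[is.na(loci)], collapse = ", "))
  }
  loci
}

#' Read an HLA genotype table
#'
#' @param path TSV with columns `sample_id`, `A1`, `A2`, `B1`, `B2`, `C1`,
#'   `C2`.
#' @return Data.frame in long form: `sample_id`, `allele`, `locus`.
#' @export
read_hla_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "A1", "A2", "B1", "B2", "C1", "C2")
  if (!all(need %in% names(df))) {
    .stopf("genotype table must have columns %s", paste(need, collapse = ", "))
  }
  genotypes_long(df)
}

#' Convert a wide genotype table to long form
#' @param df Data.frame with `sample_id` and allele columns `A1..C2`.
#' @return Long data.frame `sample_id`, `allele`, `locus`.
#' @export
genotypes_long <- function(df) {
  cols <- c("A1", "A2", "B1", "B2", "C1", "C2")
  out <- do.call(rbind, lapply(cols, function(cc) {
    data.frame(sample_id = df$sample_id, allele = df[[cc]],
               stringsAsFactors = FALSE)
  }))
  out <- out[!is.na(out$allele) & nzchar(out$allele), , drop = FALSE]
  out$locus <- hla_locus(out$allele)
  rownames(out) <- NULL
  out
}

#' Mock percentile-rank predictor
#'
#' Maps each (peptide, allele) pair deterministically and ~uniformly onto
#' (0, 100] through a pair of polynomial string hashes, so binder-fraction
#' calibration tests are platform-stable without any seed file.  Not a
#' binding-affinity model: intended for pipeline plumbing and calibration
#' checks only.
#'
#' @return A predictor object for [predict_rank()].
#' @export
mock_predictor <- function() {
  structure(list(kind = "mock"), class = "rank_predictor")
}

#' Offline rank-table predictor
#'
#' Adapter over a saved NetMHCpan-style output table.  Requires columns for
#' the peptide, the allele and the percentile rank; both the v4.0
#' (`%Rank`) and v4.1 (`EL_Rank` / `Rank_EL`) header dialects are
#' recognised, as are plain `peptide`/`allele`/`rank` headers.  A missing
#' (peptide, allele) pair raises an explicit error rather than defaulting.
#'
#' @param x Data.frame or path to a TSV.
#' @return A predictor object for [predict_rank()].
#' @export
table_predictor <- function(x) {
  df <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE, check.names = FALSE) else x
  nm <- tolower(names(df))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) .stopf("rank table lacks a recognisable %s column", what)
    df[[i]]
  }
  pep <- toupper(as.character(pick(c("peptide", "pep"), "peptide")))
  allele <- as.character(pick(c("allele", "mhc", "hla"), "allele"))
  rank <- as.numeric(pick(c("rank", "%rank", "el_rank", "rank_el", "%rank_el"), "rank"))
  tab <- setNames(rank, paste(pep, allele, sep = "|"))
  structure(list(kind = "table", table = tab), class = "rank_predictor")
}

#' Predict percentile ranks for (peptide, allele) pairs
#'
#' @param peptides,alleles Character vectors (recycled to equal length).
#' @param predictor A predictor from [mock_predictor()] or
#'   [table_predictor()].
#' @return Numeric vector of percentile ranks in (0, 100]; smaller =
#'   stronger predicted presentation.
#' @export
predict_rank <- function(peptides, alleles, predictor) {
  stopifnot(inherits(predictor, "rank_predictor"))
  n <- max(length(peptides), length(alleles))
  peptides <- rep_len(toupper(peptides), n)
  alleles <- rep_len(alleles, n)
  keys <- paste(peptides, alleles, sep = "|")
  if (predictor$kind == "mock") {
    vapply(keys, function(k) {
      h1 <- .poly_hash(k, 131, 2147483647)
      h2 <- .poly_hash(k, 1313, 2147483629)
      u <- ((h1 + 1) / 2147483648 + (h2 + 1) / 2147483630) %% 1
      r <- u * 100
      if (r == 0) 100 else r
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    r <- unname(predictor$table[keys])
    if (anyNA(r)) {
      .stopf("unscored (peptide, allele) pair(s): %s",
             paste(head(keys[is.na(r)], 5L), collapse = ", "))
    }
    r
  }
}

#' Score candidates against cohort alleles and keep binders
#'
#' Scores every candidate peptide against every distinct allele in the
#' cohort and keeps calls with `rank_percent < threshold_percent`
#' (strict: a rank exactly at the threshold is not a binder).  A peptide is
#' presented by an individual iff at least one of their alleles yields a
#' binder call for it.
#'
#' @param candidates Data.frame with a `sequence` column (peptides), or a
#'   character vector of peptides.
#' @param genotypes Long genotype data.frame (`sample_id`, `allele`) as
#'   from [read_hla_genotypes()].
#' @param threshold_percent Rank threshold (default 5.0).
#' @param predictor A `rank_predictor`.
#' @return Data.frame of binder calls: `peptide`, `allele`,
#'   `rank_percent`, `is_binder` (all TRUE).  The attribute `threshold`
#'   records the cut used.
#' @export
filter_binders <- function(candidates, genotypes, threshold_percent = 5.0,
                           predictor = mock_predictor()) {
  peptides <- if (is.data.frame(candidates)) unique(candidates$sequence) else unique(candidates)
  alleles <- unique(genotypes$allele)
  if (!length(peptides) || !length(alleles)) {
    out <- data.frame(peptide = character(0), allele = character(0),
                      rank_percent = numeric(0), is_binder = logical(0))
    attr(out, "threshold") <- threshold_percent
    return(out)
  }
  grid <- expand.grid(peptide = peptides, allele = alleles,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$rank_percent <- predict_rank(grid$peptide, grid$allele, predictor)
  grid$is_binder <- grid$rank_percent < threshold_percent
  out <- grid[grid$is_binder, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold_percent
  out
}

#' Cohort presentation statistics
#'
#' Aggregates binder calls over a genotyped cohort: distinct bound
#' peptides per allele with two detection rates (carrier fraction and
#' allele frequency; the denominator convention differs between reports,
#' so both are given), per-individual presented peptide sets, per-peptide
#' prevalence (number of individuals presenting it), the set presented by
#' every individual, and per-sample locus counts (alleles with at least
#' one presented peptide).
#'
#' @param calls Binder calls from [filter_binders()].
#' @param genotypes Long genotype data.frame (`sample_id`, `allele`,
#'   `locus`).
#' @return List with `per_allele`, `per_individual` (named list of peptide
#'   sets), `per_peptide_prevalence`, `shared_in_all`, `locus_counts`,
#'   `n_individuals`.
#' @export
summarize_cohort <- function(calls, genotypes) {
  samples <- unique(genotypes$sample_id)
  n_ind <- length(samples)
  alleles <- unique(genotypes$allele)
  per_allele <- data.frame(
    allele = alleles,
    n_bound_peptides = vapply(alleles, function(a) {
      length(unique(calls$peptide[calls$allele == a]))
    }, integer(1)),
    carrier_rate = vapply(alleles, function(a) {
      length(unique(genotypes$sample_id[genotypes$allele == a])) / n_ind
    }, numeric(1)),
    allele_frequency = vapply(alleles, function(a) {
      # copies of the allele over the 2N chromosomes of its locus
      sum(genotypes$allele == a) / (2 * n_ind)
    }, numeric(1)), row.names = NULL)
  per_individual <- lapply(setNames(samples, samples), function(s) {
    al <- genotypes$allele[genotypes$sample_id == s]
    sort(unique(calls$peptide[calls$allele %in% al]))
  })
  all_pep <- sort(unique(unlist(per_individual)))
  prevalence <- vapply(all_pep, function(p) {
    sum(vapply(per_individual, function(set) p %in% set, logical(1)))
  }, integer(1))
  per_peptide_prevalence <- data.frame(peptide = all_pep,
                                       n_individuals = unname(prevalence),
                                       row.names = NULL)
  shared_in_all <- all_pep[prevalence == n_ind]
  locus_counts <- do.call(rbind, lapply(samples, function(s) {
    gl <- genotypes[genotypes$sample_id == s, , drop = FALSE]
    present <- vapply(unique(gl$allele), function(a) {
      any(calls$allele == a)
    }, logical(1))
    pres_alleles <- unique(gl$allele)[present]
    data.frame(sample_id = s,
               n_A = sum(hla_locus(pres_alleles) == "A"),
               n_B = sum(hla_locus(pres_alleles) == "B"),
               n_C = sum(hla_locus(pres_alleles) == "C"),
               stringsAsFactors = FALSE)
  }))
  list(per_allele = per_allele, per_individual = per_individual,
       per_peptide_prevalence = per_peptide_prevalence,
       shared_in_all = shared_in_all, locus_counts = locus_counts,
       n_individuals = n_ind)
}
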