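## rMATS-style event tables: parsing, writing, significance filtering,
## differential PSI (synthetic-mode statistic), summaries and the
## PSI-expression correlation screen.
##
## Events are held in a plain data.frame with one row per event; the
## per-sample PSI vectors live in list-columns `psi_group1` / `psi_group2`
## (group 1 = old, so delta_psi = mean PSI_old - mean PSI_young).

## File-column layout per event type (spec'd rMATS JC dialect).  Internal
## coordinate columns: exon_* holds the cassette (SE), 1st exon (MXE) or
## long exon (A5SS/A3SS); exon2_* the 2nd/short exon; ri_* the merged RI
## exon; flanking_* the A5SS/A3SS flanking exon.
.rmats_coord_cols <- list(
  SE = c(exonStart_0base = "exon_start", exonEnd = "exon_end",
         upstreamES = "upstream_start", upstreamEE = "upstream_end",
         downstreamES = "downstream_start", downstreamEE = "downstream_end"),
  MXE = c(`1stExonStart_0base` = "exon_start", `1stExonEnd` = "exon_end",
          `2ndExonStart_0base` = "exon2_start", `2ndExonEnd` = "exon2_end",
          upstreamES = "upstream_start", upstreamEE = "upstream_end",
          downstreamES = "downstream_start", downstreamEE = "downstream_end"),
  A5SS = c(longExonStart_0base = "exon_start", longExonEnd = "exon_end",
           shortES = "exon2_start", shortEE = "exon2_end",
           flankingES = "flanking_start", flankingEE = "flanking_end"),
  A3SS = c(longExonStart_0base = "exon_start", longExonEnd = "exon_end",
           shortES = "exon2_start", shortEE = "exon2_end",
           flankingES = "flanking_start", flankingEE = "flanking_end"),
  RI = c(riExonStart_0base = "ri_start", riExonEnd = "ri_end",
         upstreamES = "upstream_start", upstreamEE = "upstream_end",
         downstreamES = "downstream_start", downstreamEE = "downstream_end"))

.all_coord_cols <- c("exon_start", "exon_end", "exon2_start", "exon2_end",
                     "upstream_start", "upstream_end",
                     "downstream_start", "downstream_end",
                     "flanking_start", "flanking_end", "ri_start", "ri_end")

.parse_psi_field <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE), function(v) {
    v <- suppressWarnings(as.numeric(v))
    v[!is.na(v)]  # "NA" entries are dropped, not imputed
  })
}

.empty_events <- function() {
  df <- data.frame(event_id = character(0), event_type = character(0),
                   gene_id = character(0), gene_symbol = character(0),
                   chromosome = character(0), strand = character(0),
                   stringsAsFactors = FALSE)
  for (cc in .all_coord_cols) df[[cc]] <- integer(0)
  df$ijc_sample1 <- character(0); df$sjc_sample1 <- character(0)
  df$ijc_sample2 <- character(0); df$sjc_sample2 <- character(0)
  df$inc_form_length <- integer(0); df$skip_form_length <- integer(0)
  df$p_value <- numeric(0); df$fdr <- numeric(0)
  df$psi_group1 <- list(); df$psi_group2 <- list()
  df$delta_psi <- numeric(0)
  df
}

.validate_event_coords <- function(ev) {
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    bad <- function(why) .stopf("invalid %s event %s: %s", e$event_type, e$event_id, why)
    if (e$event_type == "SE") {
      if (!(e$upstream_end <= e$exon_start && e$exon_start < e$exon_end &&
            e$exon_end <= e$downstream_start)) {
        bad("expected upstream.end <= exon.start < exon.end <= downstream.start")
      }
    } else if (e$event_type == "MXE") {
      if (!(e$exon_start < e$exon_end && e$exon2_start < e$exon2_end &&
            e$exon_end <= e$exon2_start)) bad("exon1 must precede exon2 in genomic order")
      if (!(e$upstream_end <= e$exon_start && e$exon2_end <= e$downstream_start)) {
        bad("exons must lie between the flanking exons")
      }
    } else if (e$event_type %in% c("A5SS", "A3SS")) {
      share_start <- e$exon_start == e$exon2_start
      share_end <- e$exon_end == e$exon2_end
      if (!(e$exon_start < e$exon_end && e$exon2_start < e$exon2_end)) bad("malformed interval")
      if (xor(share_start, share_end) == FALSE) {
        bad("short exon must share exactly one boundary with the long exon")
      }
      if (!(e$exon2_start >= e$exon_start && e$exon2_end <= e$exon_end)) {
        bad("short exon must be contained in the long exon")
      }
    } else if (e$event_type == "RI") {
      if (!(e$ri_start == e$upstream_start && e$ri_end == e$downstream_end &&
            e$upstream_end <= e$downstream_start)) {
        bad("ri exon must span upstream.start .. downstream.end")
      }
    }
  }
  invisible(TRUE)
}

#' Parse an rMATS junction-count (JC) table
#'
#' Reads one per-type rMATS JC TSV; comma-separated per-sample `IncLevel`
#' fields are split into numeric vectors ("NA" entries dropped from that
#' sample's vector).  Group 1 is taken as the old group, so
#' `delta_psi = mean(IncLevel1) - mean(IncLevel2)`.
#'
#' @param path Path to the table.
#' @param event_type One of SE, A5SS, A3SS, MXE, RI.
#' @return Events data.frame (see package overview) with list-columns
#'   `psi_group1`, `psi_group2`.
#' @export
parse_rmats_jc <- function(path, event_type) {
  event_type <- match.arg(event_type, AS_EVENT_TYPES)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cmap <- .rmats_coord_cols[[event_type]]
  required <- c("ID", "GeneID", "geneSymbol", "chr", "strand", names(cmap),
                "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
                "IncFormLen", "SkipFormLen", "PValue", "FDR",
                "IncLevel1", "IncLevel2", "IncLevelDifference")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    .stopf("malformed rMATS %s table '%s': missing column(s) %s",
           event_type, path, paste(missing, collapse = ", "))
  }
  ev <- data.frame(event_id = as.character(df$ID), event_type = event_type,
                   gene_id = as.character(df$GeneID),
                   gene_symbol = as.character(df$geneSymbol),
                   chromosome = as.character(df$chr),
                   strand = as.character(df$strand),
                   stringsAsFactors = FALSE)
  for (cc in .all_coord_cols) ev[[cc]] <- NA_integer_
  for (fc in names(cmap)) ev[[cmap[[fc]]]] <- as.integer(df[[fc]])
  ev$ijc_sample1 <- as.character(df$IJC_SAMPLE_1)
  ev$sjc_sample1 <- as.character(df$SJC_SAMPLE_1)
  ev$ijc_sample2 <- as.character(df$IJC_SAMPLE_2)
  ev$sjc_sample2 <- as.character(df$SJC_SAMPLE_2)
  ev$inc_form_length <- as.integer(df$IncFormLen)
  ev$skip_form_length <- as.integer(df$SkipFormLen)
  ev$p_value <- suppressWarnings(as.numeric(df$PValue))
  ev$fdr <- suppressWarnings(as.numeric(df$FDR))
  ev$psi_group1 <- .parse_psi_field(df$IncLevel1)
  ev$psi_group2 <- .parse_psi_field(df$IncLevel2)
  ev$delta_psi <- vapply(seq_len(nrow(ev)), function(i) {
    mean(ev$psi_group1[[i]]) - mean(ev$psi_group2[[i]])
  }, numeric(1))
  .validate_event_coords(ev)
  if (any(unlist(ev$psi_group1) < 0 | unlist(ev$psi_group1) > 1) ||
      any(unlist(ev$psi_group2) < 0 | unlist(ev$psi_group2) > 1)) {
    .stopf("PSI values outside [0,1] in '%s'", path)
  }
  ev
}

#' Write events in rMATS JC layout
#'
#' @param events Events data.frame (one event type).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rmats_jc <- function(events, path) {
  stopifnot(length(unique(events$event_type)) <= 1L)
  type <- events$event_type[1]
  cmap <- .rmats_coord_cols[[type]]
  fmt_psi <- function(lst) {
    vapply(lst, function(v) paste(sprintf("%.6f", v), collapse = ","), character(1))
  }
  out <- data.frame(ID = events$event_id, GeneID = events$gene_id,
                    geneSymbol = events$gene_symbol, chr = events$chromosome,
                    strand = events$strand, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (fc in names(cmap)) out[[fc]] <- events[[cmap[[fc]]]]
  out$IJC_SAMPLE_1 <- events$ijc_sample1
  out$SJC_SAMPLE_1 <- events$sjc_sample1
  out$IJC_SAMPLE_2 <- events$ijc_sample2
  out$SJC_SAMPLE_2 <- events$sjc_sample2
  out$IncFormLen <- events$inc_form_length
  out$SkipFormLen <- events$skip_form_length
  out$PValue <- events$p_value
  out$FDR <- events$fdr
  out$IncLevel1 <- fmt_psi(events$psi_group1)
  out$IncLevel2 <- fmt_psi(events$psi_group2)
  out$IncLevelDifference <- sprintf("%.6f", events$delta_psi)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter events on the significance criteria
#'
#' Keeps events with `fdr < fdr_max` AND `|delta_psi| > min_abs_dpsi`
#' (both strict), preserving input order.
#'
#' @param events Events data.frame with `fdr` and `delta_psi` populated.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param min_abs_dpsi Minimum absolute deltaPSI (default 0.1).
#' @return Filtered events data.frame.
#' @export
filter_significant <- function(events, fdr_max = 0.05, min_abs_dpsi = 0.1) {
  if (!nrow(events)) return(events)
  keep <- !is.na(events$fdr) & events$fdr < fdr_max &
    !is.na(events$delta_psi) & abs(events$delta_psi) > min_abs_dpsi
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group differential PSI test
#'
#' Two-sided test on per-sample PSI between groups, with
#' Benjamini-Hochberg FDR across all events jointly.  This is the
#' synthetic-mode statistic; real rMATS output already carries PValue/FDR.
#'
#' @param psi_matrix Numeric matrix, events x samples (rownames = event
#'   ids); `NA` entries are dropped per event.
#' @param group_labels Character/factor of length `ncol(psi_matrix)` with
#'   two levels; the first level (or `"old"`/`"group1"` if present) is
#'   group 1.
#' @param method `"t_test"` (default) or `"wilcoxon"`.
#' @return Data.frame with `event_id`, `delta_psi`, `p_value`, `fdr`.
#'   Events with fewer than 2 usable samples in either group get `NA`
#'   p/fdr and are excluded from the BH correction.
#' @export
differential_psi <- function(psi_matrix, group_labels,
                             method = c("t_test", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(is.matrix(psi_matrix), ncol(psi_matrix) == length(group_labels))
  labs <- as.character(group_labels)
  lv <- unique(labs)
  if (length(lv) != 2L) .stopf("group_labels must have exactly two levels")
  g1 <- if ("old" %in% lv) "old" else if ("group1" %in% lv) "group1" else lv[1]
  is1 <- labs == g1
  n <- nrow(psi_matrix)
  delta <- p <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    x <- psi_matrix[i, is1]; x <- x[!is.na(x)]
    y <- psi_matrix[i, !is1]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L) next
    delta[i] <- mean(x) - mean(y)
    if (var(x) + var(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
    } else if (method == "t_test") {
      p[i] <- t.test(x, y)$p.value
    } else {
      p[i] <- wilcox.test(x, y, exact = FALSE)$p.value
    }
  }
  fdr <- rep(NA_real_, n)
  ok <- !is.na(p)
  fdr[ok] <- p.adjust(p[ok], method = "BH")
  data.frame(event_id = rownames(psi_matrix) %||% as.character(seq_len(n)),
             delta_psi = delta, p_value = p, fdr = fdr,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fill PValue/FDR of an events table from its per-sample PSI
#'
#' Convenience wrapper: runs [differential_psi()] on the events'
#' `psi_group1`/`psi_group2` list-columns (all event types pooled for the
#' BH step) and writes `p_value`, `fdr` and `delta_psi` back.
#'
#' @param events Events data.frame (may mix event types).
#' @param method Passed to [differential_psi()].
#' @return Events data.frame with statistics filled in.
#' @export
add_differential_psi <- function(events, method = c("t_test", "wilcoxon")) {
  if (!nrow(events)) return(events)
  n1 <- max(lengths(events$psi_group1))
  n2 <- max(lengths(events$psi_group2))
  pad <- function(v, n) c(v, rep(NA_real_, n - length(v)))
  m <- t(vapply(seq_len(nrow(events)), function(i) {
    c(pad(events$psi_group1[[i]], n1), pad(events$psi_group2[[i]], n2))
  }, numeric(n1 + n2)))
  rownames(m) <- events$event_id
  res <- differential_psi(m, c(rep("group1", n1), rep("group2", n2)), method)
  events$delta_psi <- res$delta_psi
  events$p_value <- res$p_value
  events$fdr <- res$fdr
  events
}

#' Summarise significant events
#'
#' Counts events and distinct genes per type, splits by direction
#' (`delta_psi > 0.1` = higher usage in the old group, `< -0.1` = lower),
#' builds the per-chromosome up/down histogram and the per-gene set of
#' event types (the UpSet-style input), and reports the fraction of genes
#' carrying two or more events.
#'
#' @param events Filtered (significant) events data.frame.
#' @param direction_dpsi deltaPSI magnitude defining direction (default 0.1).
#' @return A list with elements `counts_by_type`, `direction_counts`,
#'   `chromosome_histogram`, `gene_type_overlap`, `events_per_gene`,
#'   `fraction_genes_multi_event`, `fraction_genes_multi_type`.
#' @export
summarize_events <- function(events, direction_dpsi = 0.1) {
  types <- AS_EVENT_TYPES
  if (!nrow(events)) {
    return(list(
      counts_by_type = data.frame(event_type = types, n_events = 0L, n_genes = 0L),
      direction_counts = data.frame(event_type = types, n_up = 0L, n_down = 0L),
      chromosome_histogram = data.frame(chromosome = character(0),
                                        n_up = integer(0), n_down = integer(0)),
      gene_type_overlap = data.frame(gene_id = character(0), event_types = character(0)),
      events_per_gene = data.frame(gene_id = character(0), n_events = integer(0)),
      fraction_genes_multi_event = NA_real_,
      fraction_genes_multi_type = NA_real_))
  }
  up <- events$delta_psi > direction_dpsi
  down <- events$delta_psi < -direction_dpsi
  counts_by_type <- data.frame(
    event_type = types,
    n_events = vapply(types, function(t) sum(events$event_type == t), integer(1)),
    n_genes = vapply(types, function(t) {
      length(unique(events$gene_id[events$event_type == t]))
    }, integer(1)), row.names = NULL)
  direction_counts <- data.frame(
    event_type = types,
    n_up = vapply(types, function(t) sum(up & events$event_type == t), integer(1)),
    n_down = vapply(types, function(t) sum(down & events$event_type == t), integer(1)),
    row.names = NULL)
  chroms <- sort(unique(events$chromosome))
  chromosome_histogram <- data.frame(
    chromosome = chroms,
    n_up = vapply(chroms, function(c) sum(up & events$chromosome == c), integer(1)),
    n_down = vapply(chroms, function(c) sum(down & events$chromosome == c), integer(1)),
    row.names = NULL)
  genes <- unique(events$gene_id)
  gene_type_overlap <- data.frame(
    gene_id = genes,
    event_types = vapply(genes, function(g) {
      paste(sort(unique(events$event_type[events$gene_id == g])), collapse = ",")
    }, character(1)), row.names = NULL)
  events_per_gene <- data.frame(
    gene_id = genes,
    n_events = vapply(genes, function(g) sum(events$gene_id == g), integer(1)),
    row.names = NULL)
  n_types_per_gene <- lengths(strsplit(gene_type_overlap$event_types, ",", fixed = TRUE))
  list(counts_by_type = counts_by_type,
       direction_counts = direction_counts,
       chromosome_histogram = chromosome_histogram,
       gene_type_overlap = gene_type_overlap,
       events_per_gene = events_per_gene,
       fraction_genes_multi_event = mean(events_per_gene$n_events >= 2L),
       fraction_genes_multi_type = mean(n_types_per_gene >= 2L))
}

#' PSI-expression correlation screen
#'
#' Per event, an ordinary least-squares fit of gene expression on PSI
#' across samples (equivalently a Pearson correlation with a slope
#' t-test); also returns per-type roll-ups: number of events, number
#' significant (p < 0.05), maximum and mean r-squared.
#'
#' @param psi_matrix Events x samples PSI matrix (rownames = event ids).
#' @param expression_matrix Genes x samples expression matrix (rownames =
#'   gene ids); sample columns are intersected by name.
#' @param event_gene_map Data.frame with columns `event_id`, `gene_id` and
#'   optionally `event_type`.
#' @param min_n Minimum paired observations per event (default 3).
#' @return List with `per_event` (event_id, gene_id, n, r, r_squared,
#'   p_value, skipped_reason) and `by_type` roll-up.
#' @export
psi_expression_correlation <- function(psi_matrix, expression_matrix,
                                       event_gene_map, min_n = 3L) {
  shared <- intersect(colnames(psi_matrix), colnames(expression_matrix))
  if (!length(shared)) .stopf("no shared samples between PSI and expression matrices")
  res <- lapply(seq_len(nrow(event_gene_map)), function(i) {
    eid <- event_gene_map$event_id[i]
    gid <- event_gene_map$gene_id[i]
    out <- data.frame(event_id = eid, gene_id = gid, n = NA_integer_,
                      r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                      skipped_reason = NA_character_, stringsAsFactors = FALSE)
    if (!eid %in% rownames(psi_matrix) || !gid %in% rownames(expression_matrix)) {
      out$skipped_reason <- "missing from matrix"
      return(out)
    }
    psi <- psi_matrix[eid, shared]
    expr <- expression_matrix[gid, shared]
    ok <- !is.na(psi) & !is.na(expr)
    out$n <- sum(ok)
    if (sum(ok) < min_n) {
      out$skipped_reason <- "too few paired observations"
      return(out)
    }
    if (sd(psi[ok]) == 0) {
      out$skipped_reason <- "zero-variance PSI"
      return(out)
    }
    if (sd(expr[ok]) == 0) {
      out$r <- NA_real_; out$r_squared <- 0; out$p_value <- 1
      return(out)
    }
    ct <- cor.test(psi[ok], expr[ok], method = "pearson")
    out$r <- unname(ct$estimate)
    out$r_squared <- out$r^2
    out$p_value <- ct$p.value
    out
  })
  per_event <- do.call(rbind, res)
  if ("event_type" %in% names(event_gene_map)) {
    per_event$event_type <- event_gene_map$event_type
  } else {
    per_event$event_type <- "all"
  }
  usable <- per_event[!is.na(per_event$r_squared) & is.na(per_event$skipped_reason), , drop = FALSE]
  types <- unique(per_event$event_type)
  by_type <- data.frame(
    event_type = types,
    n_events = vapply(types, function(t) sum(usable$event_type == t), integer(1)),
    n_significant = vapply(types, function(t) {
      sum(usable$event_type == t & usable$p_value < 0.05, na.rm = TRUE)
    }, integer(1)),
    max_r_squared = vapply(types, function(t) {
      v <- usable$r_squared[usable$event_type == t]
      if (length(v)) max(v) else NA_real_
    }, numeric(1)),
    mean_r_squared = vapply(types, function(t) {
      v <- usable$r_squared[usable$event_type == t]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1)), row.names = NULL)
  list(per_event = per_event, by_type = by_type)
}
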