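# Independent naive oracles, written before (and kept independent of) the
# implementations they check.

# Expected exon list after applying an event to a transcript, built by
# direct per-type interval arithmetic on the event's coordinate columns.
oracle_event_exons <- function(model, e, form) {
  ex <- model$exons
  drop_iv <- function(df, s, en) df[!(df$start == s & df$end == en), , drop = FALSE]
  add_iv <- function(df, s, en) {
    if (any(df$start == s & df$end == en)) df else rbind(df, data.frame(start = s, end = en))
  }
  out <- switch(e$event_type,
    SE = if (form == "inclusion") add_iv(ex, e$exon_start, e$exon_end)
         else drop_iv(ex, e$exon_start, e$exon_end),
    RI = if (form == "inclusion") {
      add_iv(drop_iv(drop_iv(ex, e$upstream_start, e$upstream_end),
                     e$downstream_start, e$downstream_end),
             e$ri_start, e$ri_end)
    } else ex,
    MXE = if (form == "inclusion") {
      add_iv(drop_iv(ex, e$exon2_start, e$exon2_end), e$exon_start, e$exon_end)
    } else {
      add_iv(drop_iv(ex, e$exon_start, e$exon_end), e$exon2_start, e$exon2_end)
    },
    A5SS = , A3SS = if (form == "inclusion") {
      add_iv(drop_iv(ex, e$exon2_start, e$exon2_end), e$exon_start, e$exon_end)
    } else {
      add_iv(drop_iv(ex, e$exon_start, e$exon_end), e$exon2_start, e$exon2_end)
    })
  out[order(out$start), , drop = FALSE]
}

# Naive CDS assembly: concatenate genome slices of the exon list clipped to
# the CDS bounds, reverse-complementing on the minus strand.
oracle_cds_seq <- function(exons, cds_start, cds_end, strand, genome, chrom) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pieces <- character(0)
  for (i in seq_len(nrow(exons))) {
    s <- max(exons$start[i], cds_start)
    en <- min(exons$end[i], cds_end)
    if (en > s) pieces <- c(pieces, substr(genome[[chrom]], s + 1, en))
  }
  out <- paste(pieces, collapse = "")
  if (strand == "-") {
    out <- chartr("ACGT", "TGCA",
                  paste(rev(strsplit(out, "")[[1]]), collapse = ""))
  }
  out
}

# Quadratic novel-peptide oracle: every window of the aging protein tested
# by string comparison against every window of the other protein and every
# library member.
oracle_novel <- function(p_aging, p_other, library_members, k = 9) {
  wins <- function(p) {
    n <- nchar(p)
    if (n < k) return(character(0))
    substring(p, 1:(n - k + 1), k:n)
  }
  out <- character(0)
  for (w in wins(p_aging)) {
    hit <- FALSE
    for (v in wins(p_other)) if (identical(w, v)) { hit <- TRUE; break }
    if (!hit) for (v in library_members) if (identical(w, v)) { hit <- TRUE; break }
    if (!hit) out <- c(out, w)
  }
  unique(out)
}

# Regex-free naive motif matcher: slide the pattern and test each position
# against its allowed character set.
oracle_motif_coverage <- function(sequence, sets) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  m <- length(sets)
  cov <- integer(n)
  if (n < m) return(cov)
  for (i in 1:(n - m + 1)) {
    ok <- TRUE
    for (j in 1:m) if (!chars[i + j - 1] %in% sets[[j]]) { ok <- FALSE; break }
    if (ok) cov[i:(i + m - 1)] <- 1L
  }
  cov
}

# Hand-applied Benjamini-Hochberg step-up rule.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
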