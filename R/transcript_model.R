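## Transcript models: ordered exon structures with an annotated CDS span.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id,gene_symbol Identifiers.
#' @param chromosome Chromosome name (verbatim, no prefix normalisation).
#' @param strand `"+"` or `"-"`.
#' @param exons Data.frame with columns `start`, `end`: 0-based half-open
#'   genomic intervals, non-overlapping; stored sorted genomic-ascending.
#' @param cds_start,cds_end Genomic positions bounding the annotated CDS
#'   (half-open).  For minus-strand transcripts the start codon sits at the
#'   high-coordinate end.
#' @param source One of `"reference"`, `"inclusion_variant"`,
#'   `"exclusion_variant"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_symbol, chromosome,
                             strand, exons, cds_start, cds_end,
                             source = "reference") {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) .stopf("malformed exon interval in %s", transcript_id)
  if (!.intervals_sorted_disjoint(exons)) .stopf("overlapping exons in %s", transcript_id)
  if (!is.na(cds_start) && cds_end <= cds_start) {
    .stopf("malformed CDS interval in %s", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 gene_symbol = gene_symbol, chromosome = chromosome,
                 strand = strand, exons = exons,
                 cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
                 source = source),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s %d exons, CDS [%d,%d) [%s]\n",
              x$transcript_id, x$gene_symbol, x$chromosome, x$strand,
              nrow(x$exons), x$cds_start, x$cds_end, x$source))
  invisible(x)
}

#' Spliced coding sequence of a transcript model
#'
#' Concatenates the exon slices restricted to `[cds_start, cds_end)` in
#' genomic order, then reverse-complements for minus-strand models, so the
#' result is the coding-strand CDS beginning at the annotated start codon.
#'
#' @param model A `transcript_model`.
#' @param genome Named character vector (chromosome -> DNA string).
#' @return Character CDS string (possibly `""` when the CDS is no longer
#'   covered by any exon, e.g. after surgery removed it).
#' @export
spliced_cds <- function(model, genome) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exons
  pieces <- character(0)
  for (i in seq_len(nrow(ex))) {
    s <- max(ex$start[i], model$cds_start)
    e <- min(ex$end[i], model$cds_end)
    if (e > s) pieces <- c(pieces, .genome_slice(genome, model$chromosome, s, e))
  }
  seq <- paste(pieces, collapse = "")
  if (model$strand == "-") seq <- .revcomp(seq)
  seq
}

## Full spliced transcript sequence (all exons), coding strand.
.spliced_transcript_seq <- function(model, genome) {
  ex <- model$exons
  seq <- paste(vapply(seq_len(nrow(ex)), function(i) {
    .genome_slice(genome, model$chromosome, ex$start[i], ex$end[i])
  }, character(1)), collapse = "")
  if (model$strand == "-") seq <- .revcomp(seq)
  seq
}

#' Read transcript models from a GTF annotation
#'
#' Imports gene models via `rtracklayer` and converts to the package's
#' internal 0-based half-open convention.  Transcripts without CDS features
#' get `NA` CDS bounds and are ignored by the peptide stages.
#'
#' @param path Path to a GTF file with exon and CDS features carrying
#'   `gene_id`, `transcript_id` and (optionally) `gene_name` attributes.
#' @return Named list of `transcript_model` objects (by transcript id).
#' @export
read_transcript_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start0 <- df$start - 1L  # GTF is 1-based inclusive
  ex <- df[df$type == "exon", , drop = FALSE]
  cds <- df[df$type == "CDS", , drop = FALSE]
  models <- list()
  for (tx in unique(ex$transcript_id)) {
    rows <- ex[ex$transcript_id == tx, , drop = FALSE]
    crows <- cds[cds$transcript_id == tx, , drop = FALSE]
    gene_symbol <- if ("gene_name" %in% names(rows) && !is.na(rows$gene_name[1])) {
      rows$gene_name[1]
    } else rows$gene_id[1]
    models[[tx]] <- transcript_model(
      transcript_id = tx, gene_id = rows$gene_id[1], gene_symbol = gene_symbol,
      chromosome = as.character(rows$seqnames[1]),
      strand = as.character(rows$strand[1]),
      exons = data.frame(start = rows$start0, end = rows$end),
      cds_start = if (nrow(crows)) min(crows$start0) else NA_integer_,
      cds_end = if (nrow(crows)) max(crows$end) else NA_integer_)
  }
  models
}

#' Write transcript models to a GTF annotation
#'
#' Emits gene, transcript, exon and CDS features in standard 1-based
#' inclusive GTF coordinates.
#'
#' @param models Named list of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     m$gene_id, m$transcript_id, m$gene_symbol)
    span <- c(min(m$exons$start), max(m$exons$end))
    feat <- function(type, s0, e) {
      sprintf("%s\tsplicepitope\t%s\t%d\t%d\t.\t%s\t.\t%s",
              m$chromosome, type, s0 + 1L, e, m$strand, attrs)
    }
    lines <- c(lines, feat("gene", span[1], span[2]),
               feat("transcript", span[1], span[2]))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, feat("exon", m$exons$start[i], m$exons$end[i]))
    }
    if (!is.na(m$cds_start)) {
      for (i in seq_len(nrow(m$exons))) {
        s <- max(m$exons$start[i], m$cds_start)
        e <- min(m$exons$end[i], m$cds_end)
        if (e > s) lines <- c(lines, feat("CDS", s, e))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
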