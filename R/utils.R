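## Internal helpers shared across modules.  All genomic coordinates inside the
## package are 0-based half-open ([start, end)), the rMATS/BED convention;
## GTF input/output converts at the boundary.

AS_EVENT_TYPES <- c("SE", "A5SS", "A3SS", "MXE", "RI")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                   collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.complement_chars <- function(chars) chartr("ACGTN", "TGCAN", chars)

## Extract genome[start, end) (0-based half-open) from a named character genome.
.genome_slice <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) .stopf("chromosome '%s' not in genome", chrom)
  n <- nchar(genome[[chrom]])
  start <- max(0L, start)
  end <- min(n, end)
  if (end <= start) return("")
  substr(genome[[chrom]], start + 1L, end)
}

## Interval helpers on data.frames with columns start, end (half-open).
.intervals_sorted_disjoint <- function(df) {
  if (nrow(df) < 2L) return(TRUE)
  o <- order(df$start)
  all(df$end[o][-nrow(df)] <= df$start[o][-1L])
}

## Map spliced (coding-order, 0-based) coordinates of a transcript to genomic
## 0-based positions.  Returns the full vector of genomic positions in coding
## order (5' -> 3' on the coding strand).
.coding_positions <- function(exons, strand) {
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq.int(exons$start[i], exons$end[i] - 1L)
  }), use.names = FALSE)
  if (strand == "-") pos <- rev(pos)
  pos
}

## Deterministic polynomial string hashes (exact in double arithmetic:
## intermediate products stay below 2^53).
.poly_hash <- function(s, base, mod) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * base + c) %% mod
  h
}

.non_stop_codons <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})

.stop_codons <- c("TAA", "TAG", "TGA")
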