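## Peptide engine: translation, 9-mer enumeration, background-library
## subtraction and proteomic confirmation.

#' Translate a coding sequence
#'
#' Standard genetic code, frame 0.  Translation truncates at the first stop
#' codon (the stop itself is not included); codons containing `N` translate
#' to `X`; a trailing partial codon is ignored.
#'
#' @param cds Character vector of DNA strings over `A/C/G/T/N`.
#' @return Character vector of protein strings (possibly empty strings).
#' @examples
#' translate_cds("ATGGCC")      # "MA"
#' translate_cds("ATGTAAGGG")   # "M" (stop truncation)
#' translate_cds("ATGGCNGGG")   # "MXG"
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    if (is.na(s) || nchar(s) < 3L) return("")
    if (grepl("[^ACGTN]", s)) .stopf("CDS contains characters outside A/C/G/T/N")
    n_codon <- nchar(s) %/% 3L
    starts <- seq.int(1L, by = 3L, length.out = n_codon)
    codons <- substring(s, starts, starts + 2L)
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"  # codons containing N
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Enumerate k-mer peptides with a sliding window
#'
#' Moves one residue at a time and returns `max(0, L - k + 1)` windows in
#' order.  Windows containing `X` (ambiguous translation) are excluded from
#' the result but counted in the `n_dropped_x` attribute.
#'
#' @param protein A single protein string.
#' @param k Window length in residues (default 9, MHC class I).
#' @param source_event,gene_symbol,origin_form Optional provenance carried
#'   into the output.
#' @return A data.frame with columns `sequence`, `position` (0-based start
#'   residue), `source_event`, `gene_symbol`, `origin_form`.
#' @export
kmerize <- function(protein, k = 9L, source_event = NA_character_,
                    gene_symbol = NA_character_, origin_form = NA_character_) {
  stopifnot(length(protein) == 1L, k >= 1L)
  L <- nchar(protein)
  n <- max(0L, L - as.integer(k) + 1L)
  if (n == 0L) {
    out <- data.frame(sequence = character(0), position = integer(0),
                      source_event = character(0), gene_symbol = character(0),
                      origin_form = character(0), stringsAsFactors = FALSE)
    attr(out, "n_dropped_x") <- 0L
    return(out)
  }
  seqs <- substring(protein, seq_len(n), seq_len(n) + k - 1L)
  keep <- !grepl("X", seqs, fixed = TRUE)
  out <- data.frame(sequence = seqs[keep], position = which(keep) - 1L,
                    source_event = source_event, gene_symbol = gene_symbol,
                    origin_form = origin_form, stringsAsFactors = FALSE)
  attr(out, "n_dropped_x") <- sum(!keep)
  out
}

#' Build a background peptide library
#'
#' Unions the k-mer sets of all records in the given files.  Files may be
#' protein FASTA, CDS FASTA (auto-translated when the alphabet is DNA-like),
#' or plain text with one peptide per line.
#'
#' @param paths Character vector of file paths.
#' @param k k-mer length (default 9).
#' @return An object of class `peptide_library`: a list with `members`
#'   (character set), `n_input_records`, and `provenance`.
#' @export
build_library <- function(paths, k = 9L) {
  members <- character(0)
  n_rec <- 0L
  for (p in paths) {
    if (!file.exists(p)) .stopf("cannot read peptide/FASTA file '%s'", p)
    first <- readLines(p, n = 1L)
    if (length(first) && startsWith(first, ">")) {
      ss <- Biostrings::readBStringSet(p)
      seqs <- toupper(as.character(ss))
    } else {
      seqs <- toupper(trimws(readLines(p)))
      seqs <- seqs[nzchar(seqs)]
    }
    n_rec <- n_rec + length(seqs)
    is_dna <- !grepl("[^ACGTN]", seqs)
    prot <- seqs
    if (any(is_dna)) prot[is_dna] <- translate_cds(seqs[is_dna])
    for (pr in prot) {
      if (nchar(pr) == as.integer(k) && !grepl("X", pr, fixed = TRUE)) {
        members <- c(members, pr)
      } else if (nchar(pr) > as.integer(k)) {
        members <- c(members, kmerize(pr, k)$sequence)
      }
    }
  }
  peptide_library(unique(members), provenance = paste(paths, collapse = ";"),
                  n_input_records = n_rec)
}

#' Construct a peptide library from a character set
#' @param members Character vector of peptides (deduplicated).
#' @param provenance Free-text description of the source.
#' @param n_input_records Number of source records, if known.
#' @export
peptide_library <- function(members, provenance = "", n_input_records = NA_integer_) {
  structure(list(members = unique(as.character(members)),
                 provenance = provenance,
                 n_input_records = n_input_records),
            class = "peptide_library")
}

#' @export
print.peptide_library <- function(x, ...) {
  cat(sprintf("peptide_library: %d distinct peptides (%s)\n",
              length(x$members), x$provenance))
  invisible(x)
}

#' Splice-specific novel peptides of an isoform pair
#'
#' Enumerates k-mers of the aging-favored protein, then removes every k-mer
#' present in the other form of the same event and every member of the
#' background library.  Surviving records keep event/gene/position
#' provenance and are deduplicated by (sequence, event).
#'
#' @param pair An `isoform_pair` from [build_isoform_pair()] with
#'   `cds_changed = TRUE`.
#' @param background A `peptide_library` (or character vector of peptides).
#' @param k k-mer length (default 9).
#' @return A data.frame of peptide records (possibly 0 rows).
#' @export
novel_peptides <- function(pair, background, k = 9L) {
  if (!inherits(pair, "isoform_pair")) .stopf("'pair' must be an isoform_pair")
  if (!isTRUE(pair$cds_changed)) {
    .stopf("novel_peptides() requires cds_changed = TRUE (event %s)", pair$event_id)
  }
  bg <- if (inherits(background, "peptide_library")) background$members else as.character(background)
  aging <- pair$aging_favored
  other <- setdiff(c("inclusion", "exclusion"), aging)
  prot_aging <- pair[[aging]]$protein
  prot_other <- pair[[other]]$protein
  if (!nzchar(prot_aging)) {
    return(kmerize("", k))
  }
  rec <- kmerize(prot_aging, k, source_event = pair$event_id,
                 gene_symbol = pair$gene_symbol, origin_form = aging)
  other_k <- if (nchar(prot_other) >= k) kmerize(prot_other, k)$sequence else character(0)
  keep <- !(rec$sequence %in% other_k) & !(rec$sequence %in% bg)
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[!duplicated(rec$sequence), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Confirm candidate peptides against observed proteomic peptides
#'
#' A candidate matches when an observed entry has an identical peptide
#' sequence AND an equal gene symbol (case-insensitive).  This exact-match
#' rule reproduces 100%-identity full-length matching of short peptides.
#'
#' @param candidates Data.frame of peptide records with columns `sequence`
#'   and `gene_symbol`.
#' @param observed Data.frame with columns `peptide` and `gene_symbol`.
#' @return `candidates` with an added logical `proteomic_match` column; the
#'   attribute `n_matched_sequences` holds the count of distinct matched
#'   peptide sequences.
#' @export
match_proteomics <- function(candidates, observed) {
  stopifnot(is.data.frame(candidates), is.data.frame(observed))
  if (!all(c("sequence", "gene_symbol") %in% names(candidates))) {
    .stopf("candidates must have columns 'sequence' and 'gene_symbol'")
  }
  if (nrow(observed) && !all(c("peptide", "gene_symbol") %in% names(observed))) {
    .stopf("observed list must have columns 'peptide' and 'gene_symbol'")
  }
  key_obs <- if (nrow(observed)) {
    paste(toupper(observed$peptide), toupper(observed$gene_symbol), sep = "\r")
  } else character(0)
  key_cand <- paste(toupper(candidates$sequence), toupper(candidates$gene_symbol), sep = "\r")
  candidates$proteomic_match <- key_cand %in% key_obs
  attr(candidates, "n_matched_sequences") <-
    length(unique(candidates$sequence[candidates$proteomic_match]))
  candidates
}
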