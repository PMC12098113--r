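## End-to-end convenience wrapper: significant events -> isoform pairs ->
## splice-specific candidate peptides.

#' Discover splice-specific candidate peptides for a set of events
#'
#' For each (typically significance-filtered) event: finds the compatible
#' reference transcript, builds the isoform pair, and -- when the CDS
#' changed and the aging-favored form still codes -- enumerates the novel
#' peptides surviving subtraction of the other form and the background
#' library.  Events without a matching transcript, without a CDS change,
#' or classified non-coding are skipped with a logged reason.
#'
#' @param events Events data.frame with `delta_psi` populated.
#' @param models Named list of `transcript_model`s.
#' @param genome Named character genome.
#' @param background A `peptide_library` (or character vector).
#' @param k Peptide length (default 9).
#' @return List with `candidates` (peptide records data.frame), `pairs`
#'   (named list of `isoform_pair`s by event id), and `skipped`
#'   (event_id, reason).
#' @export
discover_candidates <- function(events, models, genome, background, k = 9L) {
  pairs <- list()
  cand <- list()
  skipped <- list()
  skip <- function(eid, why) {
    skipped[[length(skipped) + 1L]] <<- data.frame(event_id = eid, reason = why,
                                                   stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(events))) {
    e <- events[i, , drop = FALSE]
    m <- match_transcript(e, models)
    if (is.null(m)) { skip(e$event_id, "no compatible transcript"); next }
    if (is.na(m$cds_start)) { skip(e$event_id, "transcript has no annotated CDS"); next }
    pair <- build_isoform_pair(m, e, genome)
    pairs[[e$event_id]] <- pair
    if (!pair$cds_changed) { skip(e$event_id, "CDS unchanged"); next }
    if (pair$frame_effect == "non_coding") { skip(e$event_id, "non-coding after surgery"); next }
    np <- novel_peptides(pair, background, k = k)
    if (nrow(np)) cand[[length(cand) + 1L]] <- np
  }
  candidates <- if (length(cand)) do.call(rbind, cand) else {
    kmerize("", k)
  }
  rownames(candidates) <- NULL
  list(candidates = candidates, pairs = pairs,
       skipped = if (length(skipped)) do.call(rbind, skipped) else {
         data.frame(event_id = character(0), reason = character(0))
       })
}
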