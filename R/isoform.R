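## Isoform "exon surgery": apply an alternative-splicing event to a
## reference transcript, extract and compare the CDS of the two forms, map
## the altered region into protein coordinates, and intersect with domains.

.has_exon <- function(exons, start, end) {
  any(exons$start == start & exons$end == end)
}

.drop_exon <- function(exons, start, end) {
  exons[!(exons$start == start & exons$end == end), , drop = FALSE]
}

.add_exon <- function(exons, start, end) {
  if (.has_exon(exons, start, end)) return(exons)
  rbind(exons, data.frame(start = start, end = end))
}

.incompatible <- function(event, model, why) {
  .stopf("event/transcript incompatible: event %s vs %s (%s)",
         event$event_id, model$transcript_id, why)
}

#' Apply a splicing event to a reference transcript
#'
#' Produces the inclusion-form or exclusion-form variant of `reference`:
#' SE keeps/removes the cassette exon; RI merges the two flanking exons and
#' the intron into the single `ri` exon (inclusion) or keeps them split
#' (exclusion); MXE keeps exon1 xor exon2; A5SS/A3SS use the long or the
#' short exon.  All other exons are copied unchanged, and the output exon
#' list is re-sorted and invariant-checked.
#'
#' @param reference A `transcript_model`.
#' @param event One event row (data.frame) as produced by
#'   [parse_rmats_jc()] or [plant_events()].
#' @param form `"inclusion"` or `"exclusion"`.
#' @return A new `transcript_model` with `source` set to the variant form.
#' @export
apply_event <- function(reference, event, form = c("inclusion", "exclusion")) {
  form <- match.arg(form)
  stopifnot(inherits(reference, "transcript_model"))
  if (is.data.frame(event)) {
    stopifnot(nrow(event) == 1L)
    event <- as.list(event)
  }
  if (!identical(as.character(event$chromosome), reference$chromosome) ||
      !identical(as.character(event$strand), reference$strand)) {
    .incompatible(event, reference, "chromosome/strand mismatch")
  }
  ex <- reference$exons
  type <- event$event_type
  span <- c(min(ex$start), max(ex$end))
  if (type %in% c("SE", "MXE", "RI")) {
    if (!.has_exon(ex, event$upstream_start, event$upstream_end) ||
        !.has_exon(ex, event$downstream_start, event$downstream_end)) {
      .incompatible(event, reference, sprintf(
        "flanking exons [%d,%d)/[%d,%d) not found in transcript exon set",
        event$upstream_start, event$upstream_end,
        event$downstream_start, event$downstream_end))
    }
  }
  if (type == "SE") {
    if (event$exon_start < span[1] || event$exon_end > span[2]) {
      .incompatible(event, reference, "cassette exon outside transcript span")
    }
    ex <- if (form == "inclusion") {
      .add_exon(ex, event$exon_start, event$exon_end)
    } else {
      .drop_exon(ex, event$exon_start, event$exon_end)
    }
  } else if (type == "RI") {
    if (form == "inclusion") {
      ex <- .drop_exon(ex, event$upstream_start, event$upstream_end)
      ex <- .drop_exon(ex, event$downstream_start, event$downstream_end)
      ex <- .add_exon(ex, event$ri_start, event$ri_end)
    }
    # exclusion keeps the two exons split: unchanged
  } else if (type == "MXE") {
    keep <- if (form == "inclusion") c(event$exon_start, event$exon_end)
            else c(event$exon2_start, event$exon2_end)
    drop <- if (form == "inclusion") c(event$exon2_start, event$exon2_end)
            else c(event$exon_start, event$exon_end)
    ex <- .drop_exon(ex, drop[1], drop[2])
    ex <- .add_exon(ex, keep[1], keep[2])
  } else if (type %in% c("A5SS", "A3SS")) {
    if (!.has_exon(ex, event$flanking_start, event$flanking_end)) {
      .incompatible(event, reference, "flanking exon not found")
    }
    long <- c(event$exon_start, event$exon_end)    # long exon
    short <- c(event$exon2_start, event$exon2_end) # short exon
    if (!.has_exon(ex, long[1], long[2]) && !.has_exon(ex, short[1], short[2])) {
      .incompatible(event, reference, "neither long nor short exon matches")
    }
    use <- if (form == "inclusion") long else short
    other <- if (form == "inclusion") short else long
    ex <- .drop_exon(ex, other[1], other[2])
    ex <- .add_exon(ex, use[1], use[2])
  } else {
    .stopf("unknown event type '%s'", type)
  }
  out <- transcript_model(
    transcript_id = reference$transcript_id, gene_id = reference$gene_id,
    gene_symbol = reference$gene_symbol, chromosome = reference$chromosome,
    strand = reference$strand, exons = ex,
    cds_start = reference$cds_start, cds_end = reference$cds_end,
    source = paste0(form, "_variant"))
  out
}

#' Find the reference transcript compatible with an event
#'
#' Transcripts must be on the event's chromosome and strand and contain the
#' event's flanking exons exactly.  When several transcripts match, the one
#' with the longest annotated CDS is used; ties break by lexicographic
#' transcript id.
#'
#' @param event One event row.
#' @param models Named list of `transcript_model` objects.
#' @return A `transcript_model`, or `NULL` when no transcript matches.
#' @export
match_transcript <- function(event, models) {
  if (is.data.frame(event)) event <- as.list(event)
  ok <- Filter(function(m) {
    if (!identical(m$chromosome, as.character(event$chromosome)) ||
        !identical(m$strand, as.character(event$strand))) return(FALSE)
    res <- try(apply_event(m, event, "inclusion"), silent = TRUE)
    !inherits(res, "try-error")
  }, models)
  if (!length(ok)) return(NULL)
  cds_len <- vapply(ok, function(m) {
    if (is.na(m$cds_start)) 0L else m$cds_end - m$cds_start
  }, integer(1))
  ids <- vapply(ok, `[[`, character(1), "transcript_id")
  ok[[order(-cds_len, ids)[1L]]]
}

#' Build the inclusion/exclusion isoform pair of an event
#'
#' Applies the event in both forms, extracts and translates both CDS, and
#' classifies the consequence.  The aging-favored form is the inclusion
#' form iff `delta_psi > 0` (deltaPSI = old - young).  `frame_effect` is
#' `"non_coding"` when the two CDS are equal, the aging-favored CDS is
#' empty, or its start codon was lost; otherwise `"preserving"` iff the CDS
#' length difference is divisible by 3.
#'
#' @param reference A `transcript_model` (the annotated transcript).
#' @param event One event row with `delta_psi` populated.
#' @param genome Named character genome.
#' @return An object of class `isoform_pair`.
#' @export
build_isoform_pair <- function(reference, event, genome) {
  if (is.data.frame(event)) event <- as.list(event)
  inc_model <- apply_event(reference, event, "inclusion")
  exc_model <- apply_event(reference, event, "exclusion")
  inc_cds <- spliced_cds(inc_model, genome)
  exc_cds <- spliced_cds(exc_model, genome)
  aging <- if (isTRUE(event$delta_psi > 0)) "inclusion" else "exclusion"
  cds_changed <- !identical(inc_cds, exc_cds)
  aging_cds <- if (aging == "inclusion") inc_cds else exc_cds
  frame_effect <- if (!cds_changed || !nzchar(aging_cds) ||
                      substr(aging_cds, 1L, 3L) != "ATG") {
    "non_coding"
  } else if ((nchar(inc_cds) - nchar(exc_cds)) %% 3L == 0L) {
    "preserving"
  } else {
    "disrupting"
  }
  pair <- structure(list(
    event_id = event$event_id, event_type = event$event_type,
    gene_id = reference$gene_id, gene_symbol = reference$gene_symbol,
    transcript_id = reference$transcript_id,
    delta_psi = event$delta_psi, aging_favored = aging,
    inclusion = list(model = inc_model, cds = inc_cds,
                     protein = translate_cds(inc_cds)),
    exclusion = list(model = exc_model, cds = exc_cds,
                     protein = translate_cds(exc_cds)),
    cds_changed = cds_changed, frame_effect = frame_effect,
    protein_interval = NULL), class = "isoform_pair")
  if (cds_changed && frame_effect != "non_coding") {
    pair$protein_interval <- map_to_protein(pair)
  }
  pair
}

#' @export
print.isoform_pair <- function(x, ...) {
  iv <- if (is.null(x$protein_interval)) "-" else
    sprintf("[%d,%d)", x$protein_interval[1], x$protein_interval[2])
  cat(sprintf("isoform_pair %s (%s, %s): cds_changed=%s frame=%s aging=%s protein_interval=%s\n",
              x$event_id, x$event_type, x$gene_symbol, x$cds_changed,
              x$frame_effect, x$aging_favored, iv))
  invisible(x)
}

#' Map the CDS difference of an isoform pair into protein coordinates
#'
#' Locates the longest common prefix/suffix of the two CDS strings and
#' converts the differing span (on the aging-favored form) to residue
#' indices `[floor(first/3), ceil(last_exclusive/3))`, clipped to the
#' translated protein length (post stop-codon truncation).  For
#' frame-disrupting events everything downstream of the first difference is
#' considered affected.
#'
#' @param pair An `isoform_pair` with `cds_changed = TRUE`.
#' @return Integer vector `c(start, end)`, 0-based half-open residues.
#' @export
map_to_protein <- function(pair) {
  stopifnot(inherits(pair, "isoform_pair"))
  if (!isTRUE(pair$cds_changed)) {
    .stopf("map_to_protein() called on identical CDS (event %s)", pair$event_id)
  }
  a <- pair[[pair$aging_favored]]$cds
  b <- pair[[setdiff(c("inclusion", "exclusion"), pair$aging_favored)]]$cds
  prot_len <- nchar(pair[[pair$aging_favored]]$protein)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  nmin <- min(length(av), length(bv))
  pre <- 0L
  while (pre < nmin && av[pre + 1L] == bv[pre + 1L]) pre <- pre + 1L
  if (abs(length(av) - length(bv)) %% 3L != 0L) {
    start <- min(pre %/% 3L, prot_len)
    return(c(start, prot_len))
  }
  suf <- 0L
  while (suf < nmin - pre &&
         av[length(av) - suf] == bv[length(bv) - suf]) suf <- suf + 1L
  last_excl <- length(av) - suf
  start <- pre %/% 3L
  end <- as.integer(ceiling(last_excl / 3))
  start <- min(start, prot_len)
  end <- min(end, prot_len)
  c(start, max(start, end))
}

#' Convert InterProScan-style domain coordinates
#'
#' InterProScan emits 1-based inclusive protein coordinates; the package
#' uses 0-based half-open.  `start` becomes `start - 1`, `end` stays.
#'
#' @param df Data.frame with columns `protein_id`, `domain_accession`,
#'   `domain_name`, `start`, `end` (1-based inclusive).
#' @return Same data.frame with 0-based half-open `start`/`end`.
#' @export
domains_from_interproscan <- function(df) {
  stopifnot(all(c("start", "end") %in% names(df)))
  df$start <- df$start - 1L
  df
}

#' Intersect event protein intervals with protein-domain annotations
#'
#' Half-open interval intersection between each pair's affected protein
#' interval and the domains annotated on the same transcript/protein; a
#' record is emitted for every non-empty intersection.  The attribute
#' `per_domain` carries the cohort roll-up (events per domain) and
#' `per_type` the number of events affecting at least one domain per event
#' type.
#'
#' @param pairs List of `isoform_pair` objects (pairs without a protein
#'   interval are skipped).
#' @param domains Data.frame with columns `protein_id` (matched against the
#'   pair's transcript id), `domain_accession`, `domain_name`, `start`,
#'   `end` (0-based half-open protein coordinates).
#' @return Data.frame with columns `event_id`, `event_type`,
#'   `domain_accession`, `domain_name`, `overlap_start`, `overlap_end`.
#' @export
overlap_domains <- function(pairs, domains) {
  out <- list()
  for (pair in pairs) {
    if (is.null(pair$protein_interval)) next
    iv <- pair$protein_interval
    dm <- domains[domains$protein_id == pair$transcript_id, , drop = FALSE]
    if (!nrow(dm)) next
    os <- pmax(iv[1], dm$start)
    oe <- pmin(iv[2], dm$end)
    hit <- oe > os
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        event_id = pair$event_id, event_type = pair$event_type,
        domain_accession = dm$domain_accession[hit],
        domain_name = dm$domain_name[hit],
        overlap_start = os[hit], overlap_end = oe[hit],
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(event_id = character(0), event_type = character(0),
               domain_accession = character(0), domain_name = character(0),
               overlap_start = integer(0), overlap_end = integer(0))
  }
  per_domain <- if (nrow(res)) {
    agg <- stats::aggregate(event_id ~ domain_accession, data = res,
                            FUN = function(x) length(unique(x)))
    names(agg)[2] <- "n_events"
    agg
  } else data.frame(domain_accession = character(0), n_events = integer(0))
  per_type <- if (nrow(res)) {
    agg <- stats::aggregate(event_id ~ event_type, data = res,
                            FUN = function(x) length(unique(x)))
    names(agg)[2] <- "n_events_affecting_domains"
    agg
  } else data.frame(event_type = character(0),
                    n_events_affecting_domains = integer(0))
  attr(res, "per_domain") <- per_domain
  attr(res, "per_type") <- per_type
  res
}
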