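## Synthetic cohort generator: a self-contained toy genome, gene models,
## planted AS events with controlled group-wise PSI shifts, background
## peptide libraries, HLA genotypes, mock proteomics and planted motif
## flanks -- with machine-readable ground truth so every downstream stage
## is testable without external data.
##
## The generator carries its own naive sequence-assembly code (direct exon
## slicing on character vectors) so that ground-truth peptides are computed
## independently of the isoform-surgery implementation they are used to
## test.

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions emulated throughout the test
#' suite: a two-group cohort (40 old vs 40 young samples), 25 signal events
#' (|deltaPSI| = 0.3) and 25 null events per event type, per-sample PSI
#' noise sd 0.05, junction depth 100 reads/event/sample, a 50% proteomic
#' capture of planted peptides with 200 decoys, and the `[ACT]ATATA` motif
#' planted at 3x the background rate of 1 placement per 250 bp flank.
#'
#' @param seed Integer seed; the generator is byte-reproducible given the
#'   full configuration.
#' @param n_chromosomes,chromosome_length Genome shape.
#' @param n_genes Number of genes; default: one per planted event plus 10.
#' @param exons_per_gene,exon_length,intron_length Integer ranges
#'   (`c(min, max)`).  Introns default to at least 260 bp so 250 bp motif
#'   flanks fit without clipping.
#' @param n_events_per_type,n_null_events_per_type Named integer vectors
#'   over SE/A5SS/A3SS/MXE/RI.
#' @param delta_psi_effect True |deltaPSI| of signal events (old - young).
#' @param psi_noise_sd Per-sample PSI noise standard deviation.
#' @param n_young,n_old Group sizes.
#' @param junction_depth Junction reads per event and sample.
#' @param frame_disrupting_fraction Fraction of signal events per type
#'   whose length change is not a multiple of 3.
#' @param se_negative_fraction Fraction of SE signal events with negative
#'   deltaPSI (exclusion favored in the old group; these carry the planted
#'   junction peptides).
#' @param proteomic_capture_fraction Fraction of planted peptides emitted
#'   into the observed proteomic list (rounded to nearest, ties down).
#' @param n_proteomic_decoys Random decoy 9-mers added to that list.
#' @param motif_pattern Degenerate motif planted in upstream-intron flanks.
#' @param motif_enrichment_fold Fold over the background placement rate in
#'   up-regulated event flanks (1 = null run).
#' @param motif_background_per_flank Background Poisson placements per
#'   250 bp flank.
#' @param k Peptide length (default 9).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L, chromosome_length = 300000L,
                       n_genes = NULL,
                       exons_per_gene = c(8L, 9L),
                       exon_length = c(90L, 150L),
                       intron_length = c(260L, 400L),
                       n_events_per_type = c(SE = 25L, A5SS = 25L, A3SS = 25L,
                                             MXE = 25L, RI = 25L),
                       n_null_events_per_type = c(SE = 25L, A5SS = 25L,
                                                  A3SS = 25L, MXE = 25L, RI = 25L),
                       delta_psi_effect = 0.3, psi_noise_sd = 0.05,
                       n_young = 40L, n_old = 40L,
                       junction_depth = 100L,
                       frame_disrupting_fraction = 0.2,
                       se_negative_fraction = 0.6,
                       proteomic_capture_fraction = 0.5,
                       n_proteomic_decoys = 200L,
                       motif_pattern = "[ACT]ATATA",
                       motif_enrichment_fold = 3,
                       motif_background_per_flank = 1,
                       k = 9L) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = if (is.null(n_genes)) NULL else as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              n_events_per_type = n_events_per_type,
              n_null_events_per_type = n_null_events_per_type,
              delta_psi_effect = delta_psi_effect, psi_noise_sd = psi_noise_sd,
              n_young = as.integer(n_young), n_old = as.integer(n_old),
              junction_depth = as.integer(junction_depth),
              frame_disrupting_fraction = frame_disrupting_fraction,
              se_negative_fraction = se_negative_fraction,
              proteomic_capture_fraction = proteomic_capture_fraction,
              n_proteomic_decoys = as.integer(n_proteomic_decoys),
              motif_pattern = motif_pattern,
              motif_enrichment_fold = motif_enrichment_fold,
              motif_background_per_flank = motif_background_per_flank,
              k = as.integer(k))
  nev <- .norm_event_counts(cfg$n_events_per_type)
  nnull <- .norm_event_counts(cfg$n_null_events_per_type)
  cfg$n_events_per_type <- nev
  cfg$n_null_events_per_type <- nnull
  if (is.null(cfg$n_genes)) cfg$n_genes <- sum(nev) + sum(nnull) + 10L
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

.norm_event_counts <- function(x) {
  out <- setNames(integer(length(AS_EVENT_TYPES)), AS_EVENT_TYPES)
  out[names(x)] <- as.integer(x)
  out
}

#' Validate a simulation configuration
#' @param cfg A `sim_config`.
#' @return `cfg` invisibly; stops with a message on the first violation.
#' @export
validate_sim_config <- function(cfg) {
  chk <- function(ok, why) if (!ok) .stopf("invalid sim_config: %s", why)
  chk(cfg$chromosome_length > 0L, "chromosome_length must be > 0")
  chk(cfg$n_chromosomes > 0L, "n_chromosomes must be > 0")
  chk(cfg$n_genes > 0L, "n_genes must be > 0")
  chk(all(cfg$exon_length > 0L) && diff(cfg$exon_length) >= 0,
      "exon_length must be a positive range")
  chk(all(cfg$intron_length > 0L) && diff(cfg$intron_length) >= 0,
      "intron_length must be a positive range")
  chk(all(cfg$exons_per_gene >= 2L) && diff(cfg$exons_per_gene) >= 0,
      "exons_per_gene must be a range with min >= 2")
  if (sum(cfg$n_events_per_type) + sum(cfg$n_null_events_per_type) > 0L) {
    chk(cfg$exons_per_gene[1] >= 8L,
        "planting events requires genes with at least 8 exons")
  }
  chk(all(c(cfg$n_events_per_type, cfg$n_null_events_per_type) >= 0L),
      "event counts must be >= 0")
  chk(cfg$delta_psi_effect > 0 && cfg$delta_psi_effect <= 1,
      "delta_psi_effect must lie in (0, 1]")
  chk(cfg$psi_noise_sd >= 0, "psi_noise_sd must be >= 0")
  chk(cfg$delta_psi_effect > 2 * cfg$psi_noise_sd,
      "delta_psi_effect must exceed 2 * psi_noise_sd (planted effects must be recoverable)")
  chk(cfg$n_young > 0L && cfg$n_old > 0L, "group sizes must be > 0")
  chk(cfg$junction_depth > 0L, "junction_depth must be > 0")
  chk(cfg$proteomic_capture_fraction >= 0 && cfg$proteomic_capture_fraction <= 1,
      "proteomic_capture_fraction must lie in [0, 1]")
  chk(cfg$motif_enrichment_fold >= 1, "motif_enrichment_fold must be >= 1")
  chk(cfg$k >= 1L, "k must be >= 1")
  invisible(cfg)
}

.genome_to_chars <- function(genome) lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
.chars_to_genome <- function(gchars) vapply(gchars, paste, character(1), collapse = "")

#' Generate a random genome
#'
#' @param config A `sim_config`.
#' @return Named character vector `chr1..chrN` of uniform-random A/C/G/T
#'   strings of the configured length; deterministic for a fixed seed.
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  setNames(vapply(seq_len(config$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chromosome_length, replace = TRUE),
          collapse = "")
  }, character(1)), paste0("chr", seq_len(config$n_chromosomes)))
}

## Role plan: one row per gene describing the event (if any) it will host.
.make_gene_plan <- function(config) {
  rows <- list()
  for (type in AS_EVENT_TYPES) {
    ns <- config$n_events_per_type[[type]]
    nn <- config$n_null_events_per_type[[type]]
    if (ns > 0L) {
      sign <- rep(1L, ns)
      if (type == "SE") {
        n_neg <- round(config$se_negative_fraction * ns)
        if (n_neg > 0L) sign[seq_len(n_neg)] <- -1L
      }
      n_dis <- round(config$frame_disrupting_fraction * ns)
      frame <- rep("preserving", ns)
      if (n_dis > 0L) {
        # for SE the disrupting subset sits among the negative (peptide) events
        cand <- if (type == "SE") which(sign < 0) else seq_len(ns)
        frame[tail(cand, min(n_dis, length(cand)))] <- "disrupting"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        role_type = type, role_class = "signal", sign = sign, frame = frame,
        stringsAsFactors = FALSE)
    }
    if (nn > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        role_type = rep(type, nn), role_class = "null", sign = 0L,
        frame = "non_coding", stringsAsFactors = FALSE)
    }
  }
  plan <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(role_type = character(0), role_class = character(0),
               sign = integer(0), frame = character(0))
  }
  n_extra <- config$n_genes - nrow(plan)
  if (n_extra < 0L) .stopf("n_genes (%d) is smaller than the number of planted events (%d)",
                           config$n_genes, nrow(plan))
  if (n_extra > 0L) {
    plan <- rbind(plan, data.frame(role_type = "none", role_class = "none",
                                   sign = 0L, frame = NA_character_)[rep(1, n_extra), ])
  }
  plan$gene_idx <- seq_len(nrow(plan))
  rownames(plan) <- NULL
  plan
}

.sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else sample(seq.int(rng[1], rng[2]), n, replace = TRUE)
}

.to_mult3 <- function(x) x - x %% 3L
.to_nonmult3 <- function(x) .to_mult3(x) + 1L

## The internal exon slot hosting each event (1-based, genomic order).
EVENT_SLOT <- 4L

#' Generate gene models over a genome
#'
#' Places non-overlapping multi-exon genes with alternating strands across
#' chromosomes and annotates each with a CDS that begins with ATG on the
#' coding strand, has length divisible by 3, and translates without an
#' internal stop (the CDS content is written back into the genome).  Genes
#' destined to host null events keep their CDS inside the first two coding
#' exons so the event region is untranslated.
#'
#' @param genome From [generate_genome()].
#' @param config The same `sim_config`.
#' @return List with `models` (named list of [transcript_model()]s, with
#'   the gene plan in `attr(models, "plan")`) and `genome` (updated).
#' @export
generate_gene_models <- function(genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  plan <- .make_gene_plan(config)
  gchars <- .genome_to_chars(genome)
  chrom_names <- names(genome)
  cursors <- setNames(rep(1000L, length(chrom_names)), chrom_names)
  models <- list()
  margin <- 1000L
  gap <- 500L
  for (gi in seq_len(nrow(plan))) {
    role <- plan[gi, ]
    m <- .sample_range(config$exons_per_gene)
    elens <- .sample_range(config$exon_length, m)
    ilens <- .sample_range(config$intron_length, m - 1L)
    k <- EVENT_SLOT
    if (role$role_class == "signal") {
      if (role$role_type == "SE") {
        elens[k] <- if (role$frame == "preserving") .to_mult3(elens[k]) else .to_nonmult3(elens[k])
      } else if (role$role_type == "MXE") {
        elens[k + 1L] <- .to_mult3(elens[k + 1L])
        elens[k] <- if (role$frame == "preserving") .to_mult3(elens[k]) else .to_nonmult3(elens[k])
      } else if (role$role_type == "RI") {
        ilens[k] <- if (role$frame == "preserving") .to_mult3(ilens[k]) else .to_nonmult3(ilens[k])
      }
    }
    ext <- 0L
    if (role$role_class != "none" && role$role_type %in% c("A5SS", "A3SS")) {
      ext <- if (identical(role$frame, "disrupting")) 31L else 3L * .sample_range(c(10L, 20L))
    }
    span <- sum(elens) + sum(ilens)
    chrom <- NA_character_
    for (try_c in chrom_names[order(cursors)]) {
      if (cursors[[try_c]] + span <= config$chromosome_length - margin) {
        chrom <- try_c; break
      }
    }
    if (is.na(chrom)) {
      .stopf("cannot place %d genes without overlap: genome too small", config$n_genes)
    }
    gstart <- cursors[[chrom]]
    cursors[[chrom]] <- gstart + span + gap
    starts <- integer(m); ends <- integer(m)
    pos <- gstart
    for (i in seq_len(m)) {
      starts[i] <- pos; ends[i] <- pos + elens[i]
      pos <- ends[i] + if (i < m) ilens[i] else 0L
    }
    strand <- if (gi %% 2L == 1L) "+" else "-"
    exons <- data.frame(start = starts, end = ends)
    # CDS in spliced (coding-order) coordinates: 12 nt 5'UTR, then the ORF
    cpos <- .coding_positions(exons, strand)
    E <- length(cpos)
    if (role$role_class == "null") {
      lens_coding <- if (strand == "+") elens else rev(elens)
      avail <- (lens_coding[1] - 12L) + lens_coding[2] %/% 2L
      cds_len <- .to_mult3(avail)
    } else {
      cds_len <- .to_mult3(E - 12L - 9L)
    }
    if (cds_len < 30L) .stopf("gene %d too short for a CDS", gi)
    cds_pos <- cpos[(12L + 1L):(12L + cds_len)]
    cds_seq_chars <- c("A", "T", "G",
                       strsplit(paste(sample(.non_stop_codons, cds_len / 3L - 1L,
                                             replace = TRUE), collapse = ""),
                                "", fixed = TRUE)[[1]])
    wchars <- if (strand == "-") .complement_chars(cds_seq_chars) else cds_seq_chars
    gchars[[chrom]][cds_pos + 1L] <- wchars
    id <- sprintf("%04d", gi)
    models[[paste0("tx_", id)]] <- transcript_model(
      transcript_id = paste0("tx_", id), gene_id = paste0("gene_", id),
      gene_symbol = paste0("GENE", id), chromosome = chrom, strand = strand,
      exons = exons, cds_start = min(cds_pos), cds_end = max(cds_pos) + 1L,
      source = "reference")
    plan$ext[gi] <- ext
  }
  attr(models, "plan") <- plan
  list(models = models, genome = .chars_to_genome(gchars))
}

## ---- generator-side naive form construction (independent of apply_event) ----

.gen_event_exons <- function(exons, e, form) {
  type <- e$event_type
  if (type == "SE") {
    if (form == "inclusion") return(exons)
    keep <- !(exons$start == e$exon_start & exons$end == e$exon_end)
    return(exons[keep, , drop = FALSE])
  }
  if (type == "RI") {
    if (form == "exclusion") return(exons)
    keep <- !((exons$start == e$upstream_start & exons$end == e$upstream_end) |
                (exons$start == e$downstream_start & exons$end == e$downstream_end))
    out <- rbind(exons[keep, , drop = FALSE],
                 data.frame(start = e$ri_start, end = e$ri_end))
    return(out[order(out$start), , drop = FALSE])
  }
  if (type == "MXE") {
    drop <- if (form == "inclusion") c(e$exon2_start, e$exon2_end) else c(e$exon_start, e$exon_end)
    keep <- !(exons$start == drop[1] & exons$end == drop[2])
    return(exons[keep, , drop = FALSE])
  }
  if (type %in% c("A5SS", "A3SS")) {
    if (form == "exclusion") return(exons)  # reference carries the short exon
    keep <- !(exons$start == e$exon2_start & exons$end == e$exon2_end)
    out <- rbind(exons[keep, , drop = FALSE],
                 data.frame(start = e$exon_start, end = e$exon_end))
    return(out[order(out$start), , drop = FALSE])
  }
  .stopf("unknown event type %s", type)
}

.gen_cds_seq <- function(gchars, chrom, exons, cds_start, cds_end, strand) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pieces <- character(0)
  for (i in seq_len(nrow(exons))) {
    s <- max(exons$start[i], cds_start); e <- min(exons$end[i], cds_end)
    if (e > s) pieces <- c(pieces, paste(gchars[[chrom]][(s + 1L):e], collapse = ""))
  }
  seq <- paste(pieces, collapse = "")
  if (strand == "-") seq <- .revcomp(seq)
  seq
}

.kmers <- function(protein, k) {
  n <- nchar(protein)
  if (n < k) return(character(0))
  kk <- substring(protein, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  kk[!grepl("X", kk, fixed = TRUE)]
}

## Event coordinate record from a gene's model + role plan.
.make_event_row <- function(model, role, event_id) {
  ex <- model$exons
  k <- EVENT_SLOT
  e <- .empty_events()[0, ]
  row <- list(event_id = event_id, event_type = role$role_type,
              gene_id = model$gene_id, gene_symbol = model$gene_symbol,
              chromosome = model$chromosome, strand = model$strand)
  for (cc in .all_coord_cols) row[[cc]] <- NA_integer_
  type <- role$role_type
  if (type == "SE") {
    row$exon_start <- ex$start[k]; row$exon_end <- ex$end[k]
    row$upstream_start <- ex$start[k - 1L]; row$upstream_end <- ex$end[k - 1L]
    row$downstream_start <- ex$start[k + 1L]; row$downstream_end <- ex$end[k + 1L]
  } else if (type == "MXE") {
    row$exon_start <- ex$start[k]; row$exon_end <- ex$end[k]
    row$exon2_start <- ex$start[k + 1L]; row$exon2_end <- ex$end[k + 1L]
    row$upstream_start <- ex$start[k - 1L]; row$upstream_end <- ex$end[k - 1L]
    row$downstream_start <- ex$start[k + 2L]; row$downstream_end <- ex$end[k + 2L]
  } else if (type == "RI") {
    row$upstream_start <- ex$start[k]; row$upstream_end <- ex$end[k]
    row$downstream_start <- ex$start[k + 1L]; row$downstream_end <- ex$end[k + 1L]
    row$ri_start <- ex$start[k]; row$ri_end <- ex$end[k + 1L]
  } else if (type %in% c("A5SS", "A3SS")) {
    ext <- role$ext
    # donor-side extension for A5SS, acceptor-side for A3SS; the genomic
    # side of each depends on the strand
    extend_right <- (type == "A5SS") == (model$strand == "+")
    if (extend_right) {
      row$exon_start <- ex$start[k]; row$exon_end <- ex$end[k] + ext
    } else {
      row$exon_start <- ex$start[k] - ext; row$exon_end <- ex$end[k]
    }
    row$exon2_start <- ex$start[k]; row$exon2_end <- ex$end[k]
    flank_right <- (type == "A5SS") == (model$strand == "+")
    if (flank_right) {
      row$flanking_start <- ex$start[k + 1L]; row$flanking_end <- ex$end[k + 1L]
    } else {
      row$flanking_start <- ex$start[k - 1L]; row$flanking_end <- ex$end[k - 1L]
    }
  }
  row
}

## Draw a stop-free in-frame insert for the inclusion form.  cds_pos is the
## coding-order genomic position vector of the inclusion-form CDS; idx are
## the 1-based indices of the insert inside it.  Returns coding-strand chars.
.draw_insert_chars <- function(gchars, chrom, strand, cds_pos, idx) {
  L <- length(idx)
  read_coding <- function(i) {
    ch <- gchars[[chrom]][cds_pos[i] + 1L]
    if (strand == "-") .complement_chars(ch) else ch
  }
  out <- character(L)
  i0 <- idx[1]
  p <- (i0 - 1L) %% 3L
  pos <- 1L
  bases <- c("A", "C", "G", "T")
  if (p > 0L) {
    prev <- read_coding((i0 - p):(i0 - 1L))
    repeat {
      cand <- sample(bases, 3L - p, replace = TRUE)
      if (!paste(c(prev, cand), collapse = "") %in% .stop_codons) break
    }
    out[pos:(pos + 3L - p - 1L)] <- cand
    pos <- pos + 3L - p
  }
  n_full <- (L - pos + 1L) %/% 3L
  if (n_full > 0L) {
    mid <- strsplit(paste(sample(.non_stop_codons, n_full, replace = TRUE),
                          collapse = ""), "", fixed = TRUE)[[1]]
    out[pos:(pos + 3L * n_full - 1L)] <- mid
    pos <- pos + 3L * n_full
  }
  r <- L - pos + 1L
  if (r > 0L) {
    after_idx <- (idx[L] + 1L):(idx[L] + 3L - r)
    nxt <- if (max(after_idx) <= length(cds_pos)) read_coding(after_idx) else character(0)
    repeat {
      cand <- sample(bases, r, replace = TRUE)
      if (length(nxt) < 3L - r ||
          !paste(c(cand, nxt), collapse = "") %in% .stop_codons) break
    }
    out[pos:L] <- cand
  }
  out
}

#' Plant alternative-splicing events into gene models
#'
#' For each event type, plants the configured number of signal events
#' (true deltaPSI = +/- `delta_psi_effect`) and null events (true deltaPSI
#' = 0, placed in untranslated regions), each on a distinct transcript.
#' Frame-preserving signal insertions (retained introns and splice-site
#' extensions) are engineered stop-free in the inclusion reading frame and
#' rejection-resampled (up to 1000 draws) until their translation yields at
#' least one 9-mer absent from the background library; ground-truth novel
#' peptides are then recorded for every signal event by brute-force
#' translation and k-mer set subtraction.
#'
#' @param models,genome From [generate_gene_models()].
#' @param config The `sim_config`.
#' @return List with `events` (events data.frame; PValue/FDR left `NA` for
#'   [add_differential_psi()]), `genome` (updated), and `truth` (list with
#'   `planted_events`, `planted_peptides`, `background`).
#' @export
plant_events <- function(models, genome, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  plan <- attr(models, "plan")
  if (is.null(plan)) .stopf("models lack the generator plan; use generate_gene_models()")
  gchars <- .genome_to_chars(genome)
  k <- config$k
  active <- plan[plan$role_class %in% c("signal", "null"), , drop = FALSE]
  type_counter <- setNames(rep(0L, length(AS_EVENT_TYPES)), AS_EVENT_TYPES)
  event_rows <- list()
  for (i in seq_len(nrow(active))) {
    role <- active[i, ]
    model <- models[[paste0("tx_", sprintf("%04d", role$gene_idx))]]
    if (nrow(model$exons) < EVENT_SLOT + 2L) {
      .stopf("transcript %s lacks an internal exon suitable for a %s event",
             model$transcript_id, role$role_type)
    }
    type_counter[role$role_type] <- type_counter[role$role_type] + 1L
    event_id <- sprintf("%s_%04d", role$role_type, type_counter[role$role_type])
    row <- .make_event_row(model, role, event_id)
    row$true_delta_psi <- role$sign * config$delta_psi_effect
    row$role_class <- role$role_class
    event_rows[[length(event_rows) + 1L]] <- c(row, list(gene_idx = role$gene_idx))
  }
  ## Background library: every reference transcript translation plus every
  ## planted event's young-favored isoform, kmerized.  Young forms never
  ## contain engineered inserts, so the library is fixed before insertion.
  ref_prot <- lapply(models, function(m) {
    translate_cds(.gen_cds_seq(gchars, m$chromosome, m$exons, m$cds_start,
                               m$cds_end, m$strand))
  })
  bg <- unique(unlist(lapply(ref_prot, .kmers, k = k), use.names = FALSE))
  young_form_of <- function(er) if (er$true_delta_psi > 0) "exclusion" else "inclusion"
  for (er in event_rows) {
    m <- models[[paste0("tx_", sprintf("%04d", er$gene_idx))]]
    yex <- .gen_event_exons(m$exons, er, young_form_of(er))
    yp <- translate_cds(.gen_cds_seq(gchars, m$chromosome, yex, m$cds_start,
                                     m$cds_end, m$strand))
    bg <- union(bg, .kmers(yp, k))
  }
  ## Engineer frame-preserving inserts, then record truth for all signal events.
  planted_peptides <- list()
  frame_effect <- character(length(event_rows))
  for (ei in seq_along(event_rows)) {
    er <- event_rows[[ei]]
    m <- models[[paste0("tx_", sprintf("%04d", er$gene_idx))]]
    role <- active[ei, ]
    if (er$role_class != "signal") {
      frame_effect[ei] <- "non_coding"
      next
    }
    aging_form <- if (er$true_delta_psi > 0) "inclusion" else "exclusion"
    other_form <- setdiff(c("inclusion", "exclusion"), aging_form)
    aex <- .gen_event_exons(m$exons, er, aging_form)
    oex <- .gen_event_exons(m$exons, er, other_form)
    insert_iv <- NULL
    if (role$role_type == "RI") {
      insert_iv <- c(er$upstream_end, er$downstream_start)
    } else if (role$role_type %in% c("A5SS", "A3SS")) {
      insert_iv <- if (er$exon_start < er$exon2_start) {
        c(er$exon_start, er$exon2_start)
      } else {
        c(er$exon2_end, er$exon_end)
      }
    }
    needs_insert <- !is.null(insert_iv) && identical(role$frame, "preserving")
    novel <- character(0)
    attempts <- 0L
    repeat {
      attempts <- attempts + 1L
      if (needs_insert) {
        cds_pos <- .coding_positions(aex, m$strand)
        cds_pos <- cds_pos[cds_pos >= m$cds_start & cds_pos < m$cds_end]
        gpos <- seq.int(insert_iv[1], insert_iv[2] - 1L)
        idx <- match(if (m$strand == "-") rev(gpos) else gpos, cds_pos)
        stopifnot(!anyNA(idx))
        chars <- .draw_insert_chars(gchars, m$chromosome, m$strand, cds_pos, idx)
        wchars <- if (m$strand == "-") .complement_chars(chars) else chars
        gchars[[m$chromosome]][cds_pos[idx] + 1L] <- wchars
      }
      aging_prot <- translate_cds(.gen_cds_seq(gchars, m$chromosome, aex,
                                               m$cds_start, m$cds_end, m$strand))
      other_prot <- translate_cds(.gen_cds_seq(gchars, m$chromosome, oex,
                                               m$cds_start, m$cds_end, m$strand))
      novel <- setdiff(setdiff(.kmers(aging_prot, k), .kmers(other_prot, k)), bg)
      if (!needs_insert || length(novel) > 0L) break
      if (attempts >= 1000L) {
        .stopf("could not engineer a library-disjoint insert for %s in 1000 attempts",
               er$event_id)
      }
    }
    len_diff <- sum(aex$end - aex$start) - sum(oex$end - oex$start)
    frame_effect[ei] <- if (len_diff %% 3L == 0L) "preserving" else "disrupting"
    planted_peptides[[er$event_id]] <- novel
  }
  ## Assemble the events data.frame.
  n_ev <- length(event_rows)
  pull_chr <- function(cc) vapply(event_rows, function(er) as.character(er[[cc]]), character(1))
  ev <- data.frame(event_id = pull_chr("event_id"), event_type = pull_chr("event_type"),
                   gene_id = pull_chr("gene_id"), gene_symbol = pull_chr("gene_symbol"),
                   chromosome = pull_chr("chromosome"), strand = pull_chr("strand"),
                   stringsAsFactors = FALSE)
  for (cc in .all_coord_cols) {
    ev[[cc]] <- vapply(event_rows, function(er) as.integer(er[[cc]]), integer(1))
  }
  ev$ijc_sample1 <- NA_character_; ev$sjc_sample1 <- NA_character_
  ev$ijc_sample2 <- NA_character_; ev$sjc_sample2 <- NA_character_
  ev$inc_form_length <- 100L
  ev$skip_form_length <- 100L
  ev$p_value <- NA_real_
  ev$fdr <- NA_real_
  ev$psi_group1 <- replicate(n_ev, numeric(0), simplify = FALSE)
  ev$psi_group2 <- replicate(n_ev, numeric(0), simplify = FALSE)
  ev$delta_psi <- NA_real_
  truth <- list(
    planted_events = data.frame(
      event_id = vapply(event_rows, `[[`, character(1), "event_id"),
      event_type = vapply(event_rows, `[[`, character(1), "event_type"),
      gene_id = vapply(event_rows, `[[`, character(1), "gene_id"),
      gene_symbol = vapply(event_rows, `[[`, character(1), "gene_symbol"),
      role_class = vapply(event_rows, `[[`, character(1), "role_class"),
      true_delta_psi = vapply(event_rows, `[[`, numeric(1), "true_delta_psi"),
      frame_effect = frame_effect, stringsAsFactors = FALSE),
    planted_peptides = planted_peptides,
    background_size = length(bg))
  list(events = ev, genome = .chars_to_genome(gchars), truth = truth)
}

#' Simulate per-sample PSI and junction counts
#'
#' Per sample, PSI = clamp(group mean + Normal(0, sd), 0, 1); the old-group
#' mean differs from the young-group mean by the event's true deltaPSI.
#' Junction counts are binomial draws at the configured depth with equal
#' inclusion/skip form lengths, so count-derived PSI matches the simulated
#' PSI in expectation.  Group 1 = old, group 2 = young.
#'
#' @param events Events from [plant_events()] (with `true_delta_psi`
#'   available in `truth$planted_events`).
#' @param truth The truth list from [plant_events()].
#' @param config The `sim_config`.
#' @return List with `events` (PSI list-columns and count strings filled;
#'   PValue/FDR left `NA`), `psi_matrix` (events x samples),
#'   `group_labels`, `sample_names`.
#' @export
simulate_psi_and_counts <- function(events, truth, config) {
  set.seed(config$seed + 3L)
  n1 <- config$n_old; n2 <- config$n_young
  samples <- c(sprintf("old_%02d", seq_len(n1)), sprintf("young_%02d", seq_len(n2)))
  labels <- c(rep("old", n1), rep("young", n2))
  psi <- matrix(NA_real_, nrow = nrow(events), ncol = n1 + n2,
                dimnames = list(events$event_id, samples))
  delta_of <- setNames(truth$planted_events$true_delta_psi,
                       truth$planted_events$event_id)
  for (i in seq_len(nrow(events))) {
    d <- delta_of[[events$event_id[i]]]
    young_mean <- if (d > 0) runif(1, 0.25, 0.45)
                  else if (d < 0) runif(1, 0.55, 0.75)
                  else runif(1, 0.3, 0.7)
    old_mean <- young_mean + d
    p1 <- .clamp(rnorm(n1, old_mean, config$psi_noise_sd), 0, 1)
    p2 <- .clamp(rnorm(n2, young_mean, config$psi_noise_sd), 0, 1)
    psi[i, ] <- c(p1, p2)
    ijc1 <- rbinom(n1, config$junction_depth, p1)
    ijc2 <- rbinom(n2, config$junction_depth, p2)
    events$psi_group1[[i]] <- p1
    events$psi_group2[[i]] <- p2
    events$ijc_sample1[i] <- paste(ijc1, collapse = ",")
    events$sjc_sample1[i] <- paste(config$junction_depth - ijc1, collapse = ",")
    events$ijc_sample2[i] <- paste(ijc2, collapse = ",")
    events$sjc_sample2[i] <- paste(config$junction_depth - ijc2, collapse = ",")
    events$delta_psi[i] <- mean(p1) - mean(p2)
  }
  list(events = events, psi_matrix = psi, group_labels = labels,
       sample_names = samples)
}

#' Build the background peptide library of a cohort
#'
#' Translates every unmodified (reference) transcript CDS plus, when the
#' planted events are supplied, every event's young-favored isoform, and
#' returns the union of their 9-mer sets.
#'
#' @param models Named list of transcript models.
#' @param genome Named character genome.
#' @param events Optional events data.frame from [plant_events()].
#' @param truth Optional truth list (for the young-favored form of each
#'   event); required when `events` is given.
#' @param k Peptide length.
#' @return A [peptide_library()].
#' @export
build_background_library <- function(models, genome, events = NULL,
                                     truth = NULL, k = 9L) {
  gchars <- .genome_to_chars(genome)
  members <- unique(unlist(lapply(models, function(m) {
    .kmers(translate_cds(.gen_cds_seq(gchars, m$chromosome, m$exons,
                                      m$cds_start, m$cds_end, m$strand)), k)
  }), use.names = FALSE))
  if (!is.null(events) && nrow(events)) {
    if (is.null(truth)) .stopf("truth is required to identify young-favored forms")
    delta_of <- setNames(truth$planted_events$true_delta_psi,
                         truth$planted_events$event_id)
    by_id <- setNames(models, vapply(models, `[[`, character(1), "transcript_id"))
    gene_to_tx <- setNames(names(by_id), vapply(models, `[[`, character(1), "gene_id"))
    for (i in seq_len(nrow(events))) {
      e <- as.list(events[i, ])
      m <- by_id[[gene_to_tx[[e$gene_id]]]]
      form <- if (delta_of[[e$event_id]] > 0) "exclusion" else "inclusion"
      yex <- .gen_event_exons(m$exons, e, form)
      yp <- translate_cds(.gen_cds_seq(gchars, m$chromosome, yex, m$cds_start,
                                       m$cds_end, m$strand))
      members <- union(members, .kmers(yp, k))
    }
  }
  peptide_library(members, provenance = "synthetic young/middle-aged background")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]

#' Simulate HLA genotypes and a proteomic capture list
#'
#' Assigns each old individual six class-I alleles drawn from a small toy
#' pool with fixed frequencies, and emits an observed proteomic peptide
#' list containing `proteomic_capture_fraction` of the planted peptides
#' (with correct gene labels; rounded to nearest, ties down) plus random
#' decoy 9-mers absent from the planted set.
#'
#' @param truth Truth list from [plant_events()] (extended in place).
#' @param config The `sim_config`.
#' @return List with `genotypes` (wide data.frame), `genotypes_long`,
#'   `observed` (peptide, gene_symbol), and the updated `truth` carrying
#'   `captured_peptides`.
#' @export
simulate_hla_and_proteomics <- function(truth, config) {
  set.seed(config$seed + 5L)
  pool <- list(
    A = c("HLA-A02:01" = 0.5, "HLA-A11:01" = 0.3, "HLA-A24:02" = 0.2),
    B = c("HLA-B07:02" = 0.4, "HLA-B08:01" = 0.35, "HLA-B40:01" = 0.25),
    C = c("HLA-C07:01" = 0.6, "HLA-C14:02" = 0.4))
  samples <- sprintf("old_%02d", seq_len(config$n_old))
  draw <- function(locus) sample(names(pool[[locus]]), 2L, replace = TRUE,
                                 prob = pool[[locus]])
  geno <- do.call(rbind, lapply(samples, function(s) {
    a <- draw("A"); b <- draw("B"); cc <- draw("C")
    data.frame(sample_id = s, A1 = a[1], A2 = a[2], B1 = b[1], B2 = b[2],
               C1 = cc[1], C2 = cc[2], stringsAsFactors = FALSE)
  }))
  pep_df <- do.call(rbind, lapply(names(truth$planted_peptides), function(eid) {
    peps <- truth$planted_peptides[[eid]]
    if (!length(peps)) return(NULL)
    gene <- truth$planted_events$gene_symbol[truth$planted_events$event_id == eid]
    data.frame(peptide = peps, gene_symbol = gene, event_id = eid,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pep_df)) {
    pep_df <- data.frame(peptide = character(0), gene_symbol = character(0),
                         event_id = character(0))
  }
  n_planted <- nrow(pep_df)
  n_cap <- as.integer(ceiling(config$proteomic_capture_fraction * n_planted - 0.5))
  cap_idx <- if (n_cap > 0L) sample.int(n_planted, n_cap) else integer(0)
  captured <- pep_df[cap_idx, , drop = FALSE]
  decoys <- character(0)
  while (length(decoys) < config$n_proteomic_decoys) {
    cand <- paste(sample(AA20, config$k, replace = TRUE), collapse = "")
    if (!cand %in% pep_df$peptide && !cand %in% decoys) decoys <- c(decoys, cand)
  }
  decoy_genes <- if (nrow(truth$planted_events)) {
    sample(unique(truth$planted_events$gene_symbol), length(decoys), replace = TRUE)
  } else rep("DECOY", length(decoys))
  observed <- rbind(captured[, c("peptide", "gene_symbol")],
                    data.frame(peptide = decoys, gene_symbol = decoy_genes,
                               stringsAsFactors = FALSE))
  observed <- observed[sample.int(nrow(observed)), , drop = FALSE]
  rownames(observed) <- NULL
  truth$captured_peptides <- captured
  list(genotypes = geno, genotypes_long = genotypes_long(geno),
       observed = observed, truth = truth)
}

#' Plant motif instances into upstream-intron flanks
#'
#' Writes concrete realizations of the degenerate motif pattern into the
#' 250 bp coding-upstream intron flank of each event's target region:
#' up-regulated signal events receive `motif_enrichment_fold` times the
#' background Poisson rate, null and down-regulated events the background
#' rate.  A3SS events are excluded entirely because their acceptor-side
#' extension occupies that flank.  Placements never cross the flank
#' boundary and are recorded with their coding-strand offsets.
#'
#' @param events Events data.frame from [plant_events()].
#' @param genome Named character genome.
#' @param config The `sim_config`.
#' @param truth Truth list from [plant_events()] (for the true deltaPSI
#'   signs); extended with `motif_placements`.
#' @return List with `genome` (updated), `placements` (data.frame), and
#'   `truth`.
#' @export
plant_motif_flanks <- function(events, genome, config, truth) {
  set.seed(config$seed + 6L)
  pat <- motif_pattern(config$motif_pattern)
  flank_len <- 250L
  if (flank_len < pat$length) .stopf("flank shorter than the motif")
  gchars <- .genome_to_chars(genome)
  delta_of <- setNames(truth$planted_events$true_delta_psi,
                       truth$planted_events$event_id)
  placements <- list()
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    if (e$event_type == "A3SS") next
    d <- delta_of[[e$event_id]]
    rate <- if (d > 0) config$motif_enrichment_fold * config$motif_background_per_flank
            else config$motif_background_per_flank
    n_place <- rpois(1L, rate)
    if (n_place == 0L) next
    tgt <- .event_target_interval(e)
    for (j in seq_len(n_place)) {
      off <- sample.int(flank_len - pat$length + 1L, 1L) - 1L
      real <- vapply(pat$sets, function(s) if (length(s) == 1L) s else sample(s, 1L),
                     character(1))
      if (e$strand == "+") {
        gpos <- (tgt[1] - flank_len + off):(tgt[1] - flank_len + off + pat$length - 1L)
        gchars[[e$chromosome]][gpos + 1L] <- real
      } else {
        gpos <- (tgt[2] + flank_len - off - 1L):(tgt[2] + flank_len - off - pat$length)
        gchars[[e$chromosome]][gpos + 1L] <- .complement_chars(real)
      }
      placements[[length(placements) + 1L]] <- data.frame(
        event_id = e$event_id, event_type = e$event_type,
        slot = "upstream_intron", offset = off,
        realization = paste(real, collapse = ""), stringsAsFactors = FALSE)
    }
  }
  placements <- if (length(placements)) do.call(rbind, placements) else {
    data.frame(event_id = character(0), event_type = character(0),
               slot = character(0), offset = integer(0),
               realization = character(0))
  }
  truth$motif_placements <- placements
  list(genome = .chars_to_genome(gchars), placements = placements, truth = truth)
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generator stages in order: genome, gene models (with CDS),
#' planted events (with engineered inserts and ground-truth peptides),
#' per-sample PSI/counts, gene-expression matrix, background peptide
#' library, HLA genotypes + proteomic capture, and motif planting.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `genome`, `models`, `events` (PValue/FDR
#'   `NA`, to be filled by [add_differential_psi()]), `psi_matrix`,
#'   `expression_matrix`, `group_labels`, `sample_names`, `background`,
#'   `genotypes`, `genotypes_long`, `observed_peptides`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  genome <- generate_genome(config)
  gm <- generate_gene_models(genome, config)
  pe <- plant_events(gm$models, gm$genome, config)
  sim <- simulate_psi_and_counts(pe$events, pe$truth, config)
  background <- build_background_library(gm$models, pe$genome, pe$events,
                                         pe$truth, k = config$k)
  hla <- simulate_hla_and_proteomics(pe$truth, config)
  mot <- plant_motif_flanks(sim$events, pe$genome, config, hla$truth)
  set.seed(config$seed + 4L)
  gene_ids <- vapply(gm$models, `[[`, character(1), "gene_id")
  expr <- t(vapply(gene_ids, function(g) {
    exp(rnorm(length(sim$sample_names), runif(1, 1, 4), 0.5))
  }, numeric(length(sim$sample_names))))
  dimnames(expr) <- list(unname(gene_ids), sim$sample_names)
  list(config = config, genome = mot$genome, models = gm$models,
       events = sim$events, psi_matrix = sim$psi_matrix,
       expression_matrix = expr, group_labels = sim$group_labels,
       sample_names = sim$sample_names, background = background,
       genotypes = hla$genotypes, genotypes_long = hla$genotypes_long,
       observed_peptides = hla$observed, truth = mot$truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the genome FASTA (60-column wrap), annotation GTF, per-type rMATS
#' JC tables, PSI and expression matrices, background library, HLA
#' genotype and proteomic TSVs, and the ground truth as JSON.
#'
#' @param cohort From [simulate_cohort()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fa <- Biostrings::DNAStringSet(cohort$genome)
  Biostrings::writeXStringSet(fa, file.path(outdir, "genome.fa"), width = 60L)
  write_transcript_gtf(cohort$models, file.path(outdir, "annotation.gtf"))
  for (type in AS_EVENT_TYPES) {
    sub <- cohort$events[cohort$events$event_type == type, , drop = FALSE]
    if (nrow(sub)) {
      write_rmats_jc(sub, file.path(outdir, sprintf("%s.MATS.JC.txt", type)))
    }
  }
  write.table(data.frame(event_id = rownames(cohort$psi_matrix),
                         cohort$psi_matrix, check.names = FALSE),
              file.path(outdir, "psi_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = rownames(cohort$expression_matrix),
                         cohort$expression_matrix, check.names = FALSE),
              file.path(outdir, "expression_matrix.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sort(cohort$background$members),
             file.path(outdir, "background_library.txt"))
  write.table(cohort$genotypes, file.path(outdir, "hla_genotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$observed_peptides, file.path(outdir, "proteomics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
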