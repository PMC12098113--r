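## RNA-binding-protein motif maps: flank extraction around events,
## position-wise motif coverage, sliding-window density profiles and
## target-vs-background positional significance curves.

.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

#' Parse a degenerate DNA motif pattern
#'
#' Accepts bracket notation (e.g. `"[ACT]ATATA"`, one character set per
#' bracketed position) and single-letter IUPAC degeneracy codes.
#'
#' @param pattern Pattern string.
#' @return Object of class `motif_pattern`: list of per-position allowed
#'   character sets, with a `length` field.
#' @export
motif_pattern <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) .stopf("unbalanced '[' in motif pattern '%s'", pattern)
      if (!length(set) || !all(set %in% c("A", "C", "G", "T", "U"))) {
        .stopf("empty or non-DNA bracket set in motif pattern '%s'", pattern)
      }
      sets[[length(sets) + 1L]] <- unique(chartr("U", "T", set))
      i <- j + 1L
    } else {
      s <- .IUPAC_SETS[[chars[i]]]
      if (is.null(s)) .stopf("unknown motif character '%s'", chars[i])
      sets[[length(sets) + 1L]] <- s
      i <- i + 1L
    }
  }
  if (length(sets) < 4L) .stopf("motif pattern must have length >= 4")
  structure(list(sets = sets, length = length(sets), pattern = pattern),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("motif_pattern '%s' (length %d)\n", x$pattern, x$length))
  invisible(x)
}

#' Position-wise motif coverage of a sequence
#'
#' Marks every position lying under at least one (possibly overlapping)
#' match of the expanded pattern; matching is exact per position against
#' the allowed character sets.
#'
#' @param sequence One DNA string.
#' @param pattern A `motif_pattern` (or pattern string).
#' @return Integer 0/1 vector of length `nchar(sequence)`.
#' @export
motif_coverage <- function(sequence, pattern) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  n <- nchar(sequence)
  m <- pattern$length
  cov <- integer(n)
  if (n < m) return(cov)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  hit <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    hit <- hit & chars[j:(n - m + j)] %in% pattern$sets[[j]]
  }
  starts <- which(hit)
  if (length(starts)) {
    d <- integer(n + 1L)
    for (s in starts) {
      d[s] <- d[s] + 1L
      d[s + m] <- d[s + m] - 1L
    }
    cov <- as.integer(cumsum(d[seq_len(n)]) > 0L)
  }
  cov
}

## Flank slot layout (simplified rMAPS-style): for each event the "target"
## region is the cassette exon (SE), the 1st exon (MXE), the long exon
## (A5SS/A3SS) or the merged retained-intron exon (RI).  Four slots are
## extracted in coding-strand orientation:
##   upstream_intron      intron_len bp immediately 5' of the target
##   target_exon_5prime   first exon_len bp of the target
##   target_exon_3prime   last exon_len bp of the target
##   downstream_intron    intron_len bp immediately 3' of the target
## Intron slots are clipped at the recorded flanking exons and at
## chromosome ends; exon slots at the target's own length.
FLANK_SLOTS <- c("upstream_intron", "target_exon_5prime",
                 "target_exon_3prime", "downstream_intron")

.event_target_interval <- function(e) {
  if (e$event_type == "RI") c(e$ri_start, e$ri_end) else c(e$exon_start, e$exon_end)
}

## Genomic bound beyond which an intron flank must be clipped (nearest
## recorded flanking-exon boundary on that side), NA when unknown.
.flank_limit <- function(e, side) {
  lims <- if (side == "left") {
    c(e$upstream_end, e$flanking_end)
  } else {
    c(e$downstream_start, e$flanking_start)
  }
  tgt <- .event_target_interval(e)
  lims <- lims[!is.na(lims)]
  if (side == "left") {
    lims <- lims[lims <= tgt[1]]
    if (length(lims)) max(lims) else NA_integer_
  } else {
    lims <- lims[lims >= tgt[2]]
    if (length(lims)) min(lims) else NA_integer_
  }
}

#' Extract exon/intron flanking regions around events
#'
#' For each event, extracts the four flank slots (see `FLANK_SLOTS`)
#' around its target region, reported 5'->3' on the coding strand.
#' Regions extending past a recorded flanking exon or a chromosome end
#' are clipped and flagged.  Events are partitioned into `up`
#' (`fdr < fdr_max` and `delta_psi > dpsi`), `down` (`< -dpsi`) and
#' `background` (the rest) sets.
#'
#' @param events Events data.frame with `fdr` and `delta_psi` populated.
#' @param genome Named character genome.
#' @param intron_len,exon_len Nominal flank lengths (defaults 250 and 50 bp).
#' @param fdr_max,dpsi Significance thresholds for the partition.
#' @return Data.frame with columns `event_id`, `event_type`, `group`,
#'   `slot`, `sequence`, `nominal_length`, `clipped`, `anchor`
#'   (`"proximal_left"` when offset 1 of the region is farthest from the
#'   target, see [density_profile()]).
#' @export
extract_flanks <- function(events, genome, intron_len = 250L, exon_len = 50L,
                           fdr_max = 0.05, dpsi = 0.1) {
  rows <- list()
  for (i in seq_len(nrow(events))) {
    e <- as.list(events[i, ])
    chrom <- as.character(e$chromosome)
    if (!chrom %in% names(genome)) next
    clen <- nchar(genome[[chrom]])
    tgt <- .event_target_interval(e)
    group <- if (!is.na(e$fdr) && e$fdr < fdr_max && !is.na(e$delta_psi)) {
      if (e$delta_psi > dpsi) "up"
      else if (e$delta_psi < -dpsi) "down"
      else "background"
    } else "background"
    left_lim <- max(0L, .flank_limit(e, "left"), na.rm = TRUE)
    right_lim <- min(clen, .flank_limit(e, "right"), na.rm = TRUE)
    ivs <- list(
      left_intron = c(max(left_lim, tgt[1] - intron_len), tgt[1]),
      exon_left = c(tgt[1], min(tgt[2], tgt[1] + exon_len)),
      exon_right = c(max(tgt[1], tgt[2] - exon_len), tgt[2]),
      right_intron = c(tgt[2], min(right_lim, tgt[2] + intron_len)))
    plus <- e$strand == "+"
    slot_of <- c(left_intron = if (plus) "upstream_intron" else "downstream_intron",
                 exon_left = if (plus) "target_exon_5prime" else "target_exon_3prime",
                 exon_right = if (plus) "target_exon_3prime" else "target_exon_5prime",
                 right_intron = if (plus) "downstream_intron" else "upstream_intron")
    for (nm in names(ivs)) {
      iv <- ivs[[nm]]
      if (iv[2] <= iv[1]) next
      seq <- .genome_slice(genome, chrom, iv[1], iv[2])
      if (!plus) seq <- .revcomp(seq)
      slot <- slot_of[[nm]]
      nominal <- if (grepl("intron", slot)) intron_len else exon_len
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = e$event_id, event_type = e$event_type, group = group,
        slot = slot, sequence = seq, nominal_length = nominal,
        clipped = nchar(seq) < nominal, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(event_id = character(0), event_type = character(0),
               group = character(0), slot = character(0),
               sequence = character(0), nominal_length = integer(0),
               clipped = logical(0))
  }
  rownames(out) <- NULL
  out
}

## Aligned coverage matrix for one slot: rows = regions, cols = offsets
## 1..nominal_length.  Clipped regions are padded with NA on the side away
## from the target region (upstream_intron / target_exon_3prime regions
## anchor at their 3' end; the other slots anchor at their 5' end).
.coverage_matrix <- function(regions, pattern) {
  L <- unique(regions$nominal_length)
  stopifnot(length(L) == 1L)
  slot <- unique(regions$slot)
  anchor_right <- length(slot) == 1L && slot %in% c("upstream_intron", "target_exon_3prime")
  m <- matrix(NA_real_, nrow = nrow(regions), ncol = L)
  for (i in seq_len(nrow(regions))) {
    cov <- motif_coverage(regions$sequence[i], pattern)
    n <- length(cov)
    if (n == 0L) next
    n <- min(n, L)
    if (anchor_right) m[i, (L - n + 1L):L] <- cov[seq_len(n)]
    else m[i, seq_len(n)] <- cov[seq_len(n)]
  }
  m
}

## Per-region windowed mean densities: rows = regions, cols = offsets
## 1..(L - window + 1).  NA propagates, so clipped regions contribute only
## to offsets they fully cover.
.window_density <- function(cov_matrix, window) {
  L <- ncol(cov_matrix)
  if (L < window) .stopf("all regions shorter than the %d bp window", window)
  n_off <- L - window + 1L
  out <- matrix(NA_real_, nrow = nrow(cov_matrix), ncol = n_off)
  kern <- rep(1, window)
  for (i in seq_len(nrow(cov_matrix))) {
    f <- stats::filter(cov_matrix[i, ], kern, sides = 1)
    out[i, ] <- as.numeric(f[window:L]) / window
  }
  out
}

#' Sliding-window motif density profile of a region set
#'
#' Per region, the windowed mean of the motif coverage vector (step 1);
#' the profile is the across-region mean at each offset.  Clipped regions
#' contribute only to offsets they cover.
#'
#' @param regions Data.frame of one flank slot from [extract_flanks()].
#' @param pattern A `motif_pattern` or pattern string.
#' @param window Window length in bp (default 50).
#' @return List with `positions` (offsets), `mean_density`, `n_regions`
#'   (per offset) — densities lie in `[0, 1]` and the profile length is
#'   `region length - window + 1`.
#' @export
density_profile <- function(regions, pattern, window = 50L) {
  if (!nrow(regions)) .stopf("density_profile() needs at least one region")
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  wd <- .window_density(.coverage_matrix(regions, pattern), window)
  list(positions = seq_len(ncol(wd)),
       mean_density = colMeans(wd, na.rm = TRUE),
       n_regions = colSums(!is.na(wd)))
}

#' Compare motif density between target and background region sets
#'
#' At each offset, a two-sided test of the per-region windowed densities
#' (target vs background): a Wilcoxon rank-sum test by default, or a label
#' permutation test on the mean difference.  Offsets with fewer than two
#' usable regions on either side get `NA` p-values.  No multiple-testing
#' correction is applied across offsets (positional p curves are reported
#' raw, as motif-map tools conventionally do); set `adjust = "BH"` to add
#' an adjusted column.
#'
#' @param target,background Region data.frames (one slot each) from
#'   [extract_flanks()].
#' @param pattern A `motif_pattern` or pattern string.
#' @param window Window length in bp (default 50).
#' @param method `"rank_sum"` (default) or `"permutation"`.
#' @param n_perm Permutations for `method = "permutation"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame with `position`, `density_target`,
#'   `density_background`, `p_value` (and `p_adjusted` if requested).
#' @export
compare_profiles <- function(target, background, pattern, window = 50L,
                             method = c("rank_sum", "permutation"),
                             n_perm = 1000L, adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!nrow(target) || !nrow(background)) {
    .stopf("both region sets must be non-empty")
  }
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  wt <- .window_density(.coverage_matrix(target, pattern), window)
  wb <- .window_density(.coverage_matrix(background, pattern), window)
  n_off <- min(ncol(wt), ncol(wb))
  p <- dt <- db <- rep(NA_real_, n_off)
  for (j in seq_len(n_off)) {
    x <- wt[, j]; x <- x[!is.na(x)]
    y <- wb[, j]; y <- y[!is.na(y)]
    dt[j] <- if (length(x)) mean(x) else NA_real_
    db[j] <- if (length(y)) mean(y) else NA_real_
    if (length(x) < 2L || length(y) < 2L) next
    if (var(c(x, y)) == 0) { p[j] <- 1; next }
    if (method == "rank_sum") {
      p[j] <- wilcox.test(x, y, exact = FALSE)$p.value
    } else {
      obs <- abs(mean(x) - mean(y))
      pool <- c(x, y)
      n1 <- length(x)
      hits <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(length(pool), n1)
        if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
      }
      p[j] <- (hits + 1) / (n_perm + 1)
    }
  }
  out <- data.frame(position = seq_len(n_off), density_target = dt,
                    density_background = db, p_value = p)
  if (adjust == "BH") out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}
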