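# Exon surgery, CDS extraction, protein-interval mapping and domain overlap.

toy_model <- function(strand = "+") {
  transcript_model("txT", "gT", "GT", "chrT", strand,
                   exons = data.frame(start = c(0L, 10L), end = c(6L, 16L)),
                   cds_start = 3L, cds_end = 13L)
}
toy_genome <- c(chrT = "ATGAAACCCGGGTTTTACGT")

test_that("spliced_cds concatenates CDS-clipped exon slices with the strand convention", {
  m <- toy_model("+")
  # exons [0,6) and [10,16), CDS [3,13) -> genome[3:6] + genome[10:13]
  expect_identical(spliced_cds(m, toy_genome), paste0("AAA", "GGT"))
  m2 <- toy_model("-")
  expect_identical(spliced_cds(m2, toy_genome),
                   chartr("ACGT", "TGCA", paste(rev(strsplit("AAAGGT", "")[[1]]), collapse = "")))
})

test_that("SE inclusion on a transcript already containing the cassette is the identity", {
  co <- small_cohort()
  ev <- co$events[co$events$event_type == "SE", ][1, ]
  m <- match_transcript(ev, co$models)
  inc <- apply_event(m, ev, "inclusion")
  expect_identical(inc$exons, m$exons)
  exc <- apply_event(m, ev, "exclusion")
  expect_identical(nrow(exc$exons), nrow(m$exons) - 1L)
  expect_identical(sum(m$exons$end - m$exons$start) - sum(exc$exons$end - exc$exons$start),
                   ev$exon_end - ev$exon_start)  # exact cassette-length delta
})

test_that("RI inclusion merges the flanking exon pair into the retained-intron exon", {
  g <- c(chrR = paste(rep("ACGT", 150), collapse = ""))
  m <- transcript_model("txR", "gR", "GR", "chrR", "+",
                        exons = data.frame(start = c(100L, 300L, 500L),
                                           end = c(200L, 400L, 560L)),
                        cds_start = 112L, cds_end = 550L)
  ev <- list(event_id = "RI_t", event_type = "RI", chromosome = "chrR", strand = "+",
             upstream_start = 100L, upstream_end = 200L,
             downstream_start = 300L, downstream_end = 400L,
             ri_start = 100L, ri_end = 400L)
  inc <- apply_event(m, ev, "inclusion")
  expect_identical(inc$exons$start, c(100L, 500L))
  expect_identical(inc$exons$end, c(400L, 560L))
  expect_identical(sum(inc$exons$end - inc$exons$start) -
                     sum(m$exons$end - m$exons$start), 100L)  # intron length
  # flank mismatch -> incompatibility error carrying coordinates
  ev_bad <- ev; ev_bad$upstream_end <- 201L; ev_bad$ri_start <- 100L
  expect_error(apply_event(m, ev_bad, "inclusion"), "incompatible")
})

test_that("surgery equals the naive exon-concatenation oracle on every planted event", {
  co <- default_cohort()
  by_gene <- setNames(co$models,
                      vapply(co$models, `[[`, character(1), "gene_id"))
  ev <- co$events
  n_checked <- 0L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    m <- by_gene[[e$gene_id]]
    for (form in c("inclusion", "exclusion")) {
      got <- spliced_cds(apply_event(m, e, form), co$genome)
      want <- oracle_cds_seq(oracle_event_exons(m, e, form), m$cds_start,
                             m$cds_end, m$strand, co$genome, m$chromosome)
      expect_identical(got, want)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 200L)
  expect_true(all(table(ev$event_type) >= 30L))
  expect_setequal(unique(ev$strand), c("+", "-"))
})

test_that("isoform pairs classify frame effects and localise the protein change", {
  co <- default_cohort()
  tr <- co$truth$planted_events
  sig <- merge(add_differential_psi(co$events), tr[tr$role_class == "signal", ],
               by = "event_id")
  by_gene <- setNames(co$models, vapply(co$models, `[[`, character(1), "gene_id"))
  checked_preserving <- 0L
  for (i in seq_len(nrow(sig))) {
    e <- sig[i, ]
    names(e)[names(e) == "event_type.x"] <- "event_type"
    names(e)[names(e) == "gene_id.x"] <- "gene_id"
    pair <- build_isoform_pair(by_gene[[e$gene_id]], e, co$genome)
    expect_true(pair$cds_changed)
    expect_identical(pair$frame_effect, e$frame_effect)
    if (pair$frame_effect == "preserving" && checked_preserving < 40L) {
      # proteins agree outside the mapped interval
      iv <- pair$protein_interval
      pa <- strsplit(pair[[pair$aging_favored]]$protein, "")[[1]]
      po <- strsplit(pair[[setdiff(c("inclusion", "exclusion"),
                                   pair$aging_favored)]]$protein, "")[[1]]
      shift <- length(pa) - length(po)
      if (iv[1] > 0) expect_identical(pa[seq_len(iv[1])], po[seq_len(iv[1])])
      if (iv[2] < length(pa)) {
        expect_identical(pa[(iv[2] + 1):length(pa)],
                         po[(iv[2] + 1 - shift):length(po)])
      }
      checked_preserving <- checked_preserving + 1L
    }
  }
  expect_gte(checked_preserving, 40L)
})

test_that("UTR-only events leave the CDS unchanged", {
  co <- default_cohort()
  tr <- co$truth$planted_events
  nulls <- add_differential_psi(co$events)
  nulls <- nulls[nulls$event_id %in% tr$event_id[tr$role_class == "null"], ]
  by_gene <- setNames(co$models, vapply(co$models, `[[`, character(1), "gene_id"))
  for (i in seq_len(min(10L, nrow(nulls)))) {
    e <- nulls[i, ]
    pair <- build_isoform_pair(by_gene[[e$gene_id]], e, co$genome)
    expect_false(pair$cds_changed)
  }
})

test_that("protein-interval arithmetic follows the floor/ceil rule and frameshift semantics", {
  # difference confined to CDS positions 30..35 -> residues [10, 12)
  base <- paste(rep("ATGGCTGCA", 10), collapse = "")   # 90 nt, no stops
  alt <- base
  substr(alt, 31, 36) <- "TTTTTT"
  pair <- structure(list(event_id = "t", cds_changed = TRUE, aging_favored = "inclusion",
                         inclusion = list(cds = alt, protein = translate_cds(alt)),
                         exclusion = list(cds = base, protein = translate_cds(base))),
                    class = "isoform_pair")
  expect_identical(map_to_protein(pair), c(10L, 12L))
  # frame disruption starting at nucleotide 31 -> [10, protein_length)
  alt2 <- paste0(substr(base, 1, 30), "T", substr(base, 31, 90))
  pair2 <- structure(list(event_id = "t2", cds_changed = TRUE, aging_favored = "inclusion",
                          inclusion = list(cds = alt2, protein = translate_cds(alt2)),
                          exclusion = list(cds = base, protein = translate_cds(base))),
                     class = "isoform_pair")
  iv <- map_to_protein(pair2)
  expect_identical(iv[1], 10L)
  expect_identical(iv[2], nchar(translate_cds(alt2)))
  # identical CDS -> contract violation
  pair3 <- pair; pair3$cds_changed <- FALSE
  expect_error(map_to_protein(pair3), "identical CDS")
})

test_that("domain overlap uses half-open intersection and matches a quadratic oracle", {
  mk_pair <- function(id, iv) {
    structure(list(event_id = id, event_type = "SE", transcript_id = "txD",
                   protein_interval = iv), class = "isoform_pair")
  }
  domains <- data.frame(protein_id = "txD",
                        domain_accession = c("PF1", "PF2"),
                        domain_name = c("d1", "d2"),
                        start = c(0L, 12L), end = c(50L, 30L))
  res <- overlap_domains(list(mk_pair("e1", c(10L, 12L))), domains)
  expect_identical(nrow(res), 1L)  # [10,12) vs [12,30): half-open abutment, no hit
  expect_identical(res$domain_accession, "PF1")
  expect_identical(c(res$overlap_start, res$overlap_end), c(10L, 12L))
  # quadratic oracle over random pairs/domains
  set.seed(7)
  pairs <- lapply(1:40, function(i) {
    s <- sample(0:90, 1); mk_pair(paste0("p", i), c(s, s + sample(1:10, 1)))
  })
  doms <- data.frame(protein_id = "txD", domain_accession = paste0("D", 1:15),
                     domain_name = paste0("D", 1:15),
                     start = sample(0:80, 15, TRUE), end = 0L)
  doms$end <- doms$start + sample(5:20, 15, TRUE)
  res <- overlap_domains(pairs, doms)
  brute <- 0L
  for (p in pairs) for (j in seq_len(nrow(doms))) {
    if (min(p$protein_interval[2], doms$end[j]) > max(p$protein_interval[1], doms$start[j])) {
      brute <- brute + 1L
    }
  }
  expect_identical(nrow(res), brute)
  per_dom <- attr(res, "per_domain")
  for (j in seq_len(nrow(per_dom))) {
    dj <- doms[doms$domain_accession == per_dom$domain_accession[j], ]
    cnt <- sum(vapply(pairs, function(p) {
      min(p$protein_interval[2], dj$end) > max(p$protein_interval[1], dj$start)
    }, logical(1)))
    expect_identical(per_dom$n_events[j], cnt)
  }
  # InterProScan converter shifts starts only
  conv <- domains_from_interproscan(data.frame(protein_id = "x",
                                               domain_accession = "PF",
                                               domain_name = "d",
                                               start = 5L, end = 30L))
  expect_identical(c(conv$start, conv$end), c(4L, 30L))
})
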