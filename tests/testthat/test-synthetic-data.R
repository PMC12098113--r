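# The cohort generator: determinism, construction contracts, and ground
# truth consistency.

test_that("genome generation is deterministic, seed-sensitive and validated", {
  cfg <- sim_config(seed = 1L, n_chromosomes = 2L, chromosome_length = 50000L,
                    n_events_per_type = c(SE = 0L), n_null_events_per_type = c(SE = 0L),
                    n_genes = 5L, exons_per_gene = c(4L, 5L))
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  expect_length(g1, 2L)
  expect_true(all(nchar(g1) == 50000L))
  expect_false(any(grepl("[^ACGT]", g1)))
  cfg2 <- cfg; cfg2$seed <- 2L
  expect_false(identical(g1, generate_genome(cfg2)))
  expect_error(sim_config(chromosome_length = 0L), "chromosome_length")
  expect_error(sim_config(psi_noise_sd = 0.2), "recoverable")
})

test_that("gene models satisfy the CDS construction contract", {
  co <- small_cohort()
  for (m in co$models) {
    expect_true(nrow(m$exons) >= 8L)
    expect_true(all(diff(m$exons$start) > 0))             # genomic-ascending
    expect_true(all(m$exons$end[-nrow(m$exons)] <= m$exons$start[-1]))
    cds <- spliced_cds(m, co$genome)
    expect_identical(substr(cds, 1, 3), "ATG")
    expect_identical(nchar(cds) %% 3, 0)
    expect_false(grepl("[*]", translate_cds(cds)))        # no internal stop
  }
  strands <- vapply(co$models, `[[`, character(1), "strand")
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("minus-strand CDS is the reverse complement of the genomic concatenation", {
  co <- small_cohort()
  minus <- Filter(function(m) m$strand == "-", co$models)[[1]]
  plus_read <- oracle_cds_seq(minus$exons, minus$cds_start, minus$cds_end,
                              "+", co$genome, minus$chromosome)
  expect_identical(spliced_cds(minus, co$genome),
                   chartr("ACGT", "TGCA",
                          paste(rev(strsplit(plus_read, "")[[1]]), collapse = "")))
})

test_that("planted events target distinct transcripts and record frame effects", {
  co <- default_cohort()
  tr <- co$truth$planted_events
  expect_identical(nrow(tr), 250L)
  expect_identical(anyDuplicated(tr$gene_id), 0L)
  expect_identical(anyDuplicated(tr$event_id), 0L)
  # length rule: frame effect matches the planted segment length mod 3
  ev <- co$events
  se <- merge(ev[ev$event_type == "SE", ], tr, by = "event_id")
  se_sig <- se[se$role_class == "signal", ]
  expect_identical(se_sig$frame_effect == "preserving",
                   (se_sig$exon_end - se_sig$exon_start) %% 3L == 0L)
  ri <- merge(ev[ev$event_type == "RI", ], tr, by = "event_id")
  ri_sig <- ri[ri$role_class == "signal", ]
  expect_identical(ri_sig$frame_effect == "preserving",
                   (ri_sig$downstream_start - ri_sig$upstream_end) %% 3L == 0L)
  # null events are placed outside the CDS and classified non-coding
  expect_true(all(tr$frame_effect[tr$role_class == "null"] == "non_coding"))
  expect_true(all(tr$true_delta_psi[tr$role_class == "null"] == 0))
  expect_true(all(abs(tr$true_delta_psi[tr$role_class == "signal"]) == 0.3))
})

test_that("every frame-preserving insert event contributes novel peptides disjoint from the background", {
  co <- default_cohort()
  tr <- co$truth$planted_events
  planted <- unlist(co$truth$planted_peptides, use.names = FALSE)
  expect_true(length(planted) > 0)
  expect_length(intersect(planted, co$background$members), 0L)
  # engineered insert types always yield at least one novel 9-mer
  ins <- tr$event_id[tr$role_class == "signal" & tr$frame_effect == "preserving" &
                       tr$event_type %in% c("RI", "A5SS", "A3SS")]
  expect_true(all(lengths(co$truth$planted_peptides[ins]) >= 1L))
})

test_that("simulated PSI respects clamping and the planted group separation", {
  co <- default_cohort()
  psi <- co$psi_matrix
  expect_true(all(psi >= 0 & psi <= 1))
  tr <- co$truth$planted_events
  old <- co$group_labels == "old"
  emp_delta <- rowMeans(psi[, old]) - rowMeans(psi[, !old])
  tol <- 3 * co$config$psi_noise_sd / sqrt(sum(old))
  for (cls in c("signal", "null")) {
    ids <- tr$event_id[tr$role_class == cls]
    expect_true(all(abs(emp_delta[ids] - tr$true_delta_psi[match(ids, tr$event_id)])
                    < 4 * tol))
  }
  # count-derived PSI tracks simulated PSI (equal form lengths)
  ev <- co$events[1, ]
  ijc <- as.numeric(strsplit(ev$ijc_sample1, ",")[[1]])
  sjc <- as.numeric(strsplit(ev$sjc_sample1, ",")[[1]])
  expect_true(mean(abs(ijc / (ijc + sjc) - ev$psi_group1[[1]])) < 0.2)
})

test_that("proteomic capture obeys the rounding contract and gene labels match truth", {
  co <- default_cohort()
  n_planted <- sum(lengths(co$truth$planted_peptides))
  expect_identical(nrow(co$truth$captured_peptides),
                   as.integer(ceiling(0.5 * n_planted - 0.5)))
  cap <- co$truth$captured_peptides
  tr <- co$truth$planted_events
  expect_identical(cap$gene_symbol,
                   tr$gene_symbol[match(cap$event_id, tr$event_id)])
  # every captured peptide appears in the observed list
  expect_true(all(cap$peptide %in% co$observed_peptides$peptide))
  # zero capture -> decoys only
  hz <- simulate_hla_and_proteomics(
    local({ t <- co$truth; t$captured_peptides <- NULL; t }),
    local({ c <- co$config; c$proteomic_capture_fraction <- 0; c }))
  expect_identical(nrow(hz$truth$captured_peptides), 0L)
  expect_false(any(hz$observed$peptide %in% unlist(co$truth$planted_peptides)))
})

test_that("motif placements stay inside the coding-upstream intron flank", {
  co <- default_cohort()
  pl <- co$truth$motif_placements
  expect_true(nrow(pl) > 0)
  expect_true(all(pl$offset >= 0 & pl$offset <= 250 - 6))
  expect_false(any(pl$event_type == "A3SS"))
  # audit: the planted realization is readable at the recorded offset of
  # the extracted coding-strand flank
  ev <- add_differential_psi(co$events)
  fl <- extract_flanks(ev, co$genome)
  ui <- fl[fl$slot == "upstream_intron", ]
  for (i in seq_len(min(25L, nrow(pl)))) {
    reg <- ui$sequence[ui$event_id == pl$event_id[i]]
    expect_identical(substr(reg, pl$offset[i] + 1, pl$offset[i] + 6),
                     pl$realization[i])
  }
  # up-events carry ~fold-times the background placement count
  tr <- co$truth$planted_events
  up <- tr$event_id[tr$true_delta_psi > 0 & tr$event_type != "A3SS"]
  null <- tr$event_id[tr$role_class == "null" & tr$event_type != "A3SS"]
  rate_up <- sum(pl$event_id %in% up) / length(up)
  rate_null <- sum(pl$event_id %in% null) / length(null)
  expect_gt(rate_up, 2 * rate_null)
})

test_that("the emitted cohort files round-trip and conserve planted events", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  seen <- character(0)
  for (type in c("SE", "A5SS", "A3SS", "MXE", "RI")) {
    ev <- parse_rmats_jc(file.path(dir, sprintf("%s.MATS.JC.txt", type)), type)
    seen <- c(seen, ev$event_id)
  }
  expect_setequal(seen, co$truth$planted_events$event_id)
  expect_identical(anyDuplicated(seen), 0L)
  models <- read_transcript_gtf(file.path(dir, "annotation.gtf"))
  expect_setequal(names(models), names(co$models))
  m <- co$models[[5]]
  expect_identical(models[[m$transcript_id]]$exons, m$exons)
  expect_identical(models[[m$transcript_id]]$cds_start, m$cds_start)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa[["chr1"]]), unname(co$genome["chr1"]))
})
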