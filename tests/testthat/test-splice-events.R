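# rMATS-table parsing, significance filtering, differential PSI and the
# event-level summaries.

make_se_table <- function(path, inc1 = "0.8,0.7,NA", inc2 = "0.4,0.5") {
  df <- data.frame(ID = "SE_X", GeneID = "g1", geneSymbol = "G1", chr = "chr1",
                   strand = "+", exonStart_0base = 500L, exonEnd = 590L,
                   upstreamES = 100L, upstreamEE = 200L,
                   downstreamES = 800L, downstreamEE = 900L,
                   IJC_SAMPLE_1 = "10,9,0", SJC_SAMPLE_1 = "2,3,0",
                   IJC_SAMPLE_2 = "5,5", SJC_SAMPLE_2 = "5,5",
                   IncFormLen = 100L, SkipFormLen = 100L,
                   PValue = 0.001, FDR = 0.01,
                   IncLevel1 = inc1, IncLevel2 = inc2,
                   IncLevelDifference = 0.3, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("parsing splits IncLevel fields, drops NA entries and computes deltaPSI", {
  path <- make_se_table(withr::local_tempfile(fileext = ".txt"))
  ev <- parse_rmats_jc(path, "SE")
  expect_identical(ev$psi_group1[[1]], c(0.8, 0.7))
  expect_identical(ev$psi_group2[[1]], c(0.4, 0.5))
  expect_equal(ev$delta_psi, 0.30, tolerance = 1e-9)
  expect_identical(ev$fdr, 0.01)
})

test_that("malformed tables and coordinate violations are rejected with informative errors", {
  path <- make_se_table(withr::local_tempfile(fileext = ".txt"))
  df <- read.delim(path, check.names = FALSE)
  df$FDR <- NULL
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_rmats_jc(path, "SE"), "FDR")
  # cassette exon overlapping its upstream flank
  path2 <- make_se_table(withr::local_tempfile(fileext = ".txt"))
  df <- read.delim(path2, check.names = FALSE)
  df$exonStart_0base <- 150L
  write.table(df, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_rmats_jc(path2, "SE"), "SE_X")
  # PSI outside [0,1]
  path3 <- make_se_table(withr::local_tempfile(fileext = ".txt"), inc1 = "1.4,0.5")
  expect_error(parse_rmats_jc(path3, "SE"), "PSI")
})

test_that("A5SS short exon must share exactly one boundary with the long exon", {
  co <- small_cohort()
  a5 <- co$events[co$events$event_type == "A5SS", ][1, ]
  expect_true(a5$exon2_start == a5$exon_start || a5$exon2_end == a5$exon_end)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "a5.txt")
  write_rmats_jc(co$events[co$events$event_type == "A5SS", ], f)
  expect_silent(parse_rmats_jc(f, "A5SS"))
  bad <- read.delim(f, check.names = FALSE)
  bad$shortES <- bad$longExonStart_0base + 1L
  bad$shortEE <- bad$longExonEnd - 1L
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_rmats_jc(f, "A5SS"), "boundary")
})

test_that("a planted event table round-trips through write and parse", {
  co <- small_cohort()
  sim <- co$events[co$events$event_type == "MXE", ]
  f <- withr::local_tempfile(fileext = ".txt")
  write_rmats_jc(sim, f)
  back <- parse_rmats_jc(f, "MXE")
  expect_identical(back$event_id, sim$event_id)
  for (cc in c("exon_start", "exon_end", "exon2_start", "exon2_end",
               "upstream_start", "upstream_end", "downstream_start",
               "downstream_end", "inc_form_length")) {
    expect_identical(back[[cc]], sim[[cc]])
  }
  expect_equal(unlist(back$psi_group1), unlist(sim$psi_group1), tolerance = 1e-6)
})

test_that("significance filtering is strict on both thresholds and order-preserving", {
  ev <- data.frame(event_id = c("a", "b", "c", "d"),
                   fdr = c(0.04, 0.04, 0.05, 0.01),
                   delta_psi = c(0.15, 0.10, 0.50, -0.2))
  kept <- filter_significant(ev)
  expect_identical(kept$event_id, c("a", "d"))   # 0.10 and fdr 0.05 excluded
  expect_identical(filter_significant(kept), kept)  # idempotent
  # commutes with concatenation
  expect_identical(filter_significant(rbind(ev, ev))$event_id, c("a", "d", "a", "d"))
  expect_identical(nrow(filter_significant(ev[0, ])), 0L)
})

test_that("differential PSI handles degenerate and separated groups and applies BH", {
  m <- rbind(e1 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
             e2 = c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1))
  res <- differential_psi(m, c("old", "old", "old", "young", "young", "young"))
  expect_identical(res$p_value[1], 1)
  expect_identical(res$delta_psi[1], 0)
  expect_equal(res$delta_psi[2], 0.8)
  expect_lt(res$p_value[2], 1e-6)
  # too few usable samples -> NA, excluded from BH
  m2 <- rbind(e1 = c(0.2, NA, NA, 0.4, 0.5, 0.6), e2 = m[2, ])
  res2 <- differential_psi(m2, c("old", "old", "old", "young", "young", "young"))
  expect_true(is.na(res2$p_value[1]) && is.na(res2$fdr[1]))
  expect_false(is.na(res2$fdr[2]))
})

test_that("the joint FDR column equals the hand-applied step-up rule", {
  co <- small_cohort()
  ev <- add_differential_psi(co$events)
  ok <- !is.na(ev$p_value)
  expect_equal(ev$fdr[ok], oracle_bh(ev$p_value[ok]), tolerance = 1e-12)
  # monotone after sorting by p
  o <- order(ev$p_value[ok])
  expect_true(all(diff(ev$fdr[ok][o]) >= -1e-12))
})

test_that("event summaries count events, genes, directions and chromosomes conservatively", {
  ev <- data.frame(
    event_id = paste0("e", 1:5),
    event_type = c("SE", "SE", "SE", "RI", "RI"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    chromosome = c("chr1", "chr1", "chr2", "chr2", "chr2"),
    delta_psi = c(0.3, 0.2, 0.4, -0.3, 0.2), fdr = 0.01)
  s <- summarize_events(ev)
  cb <- s$counts_by_type
  expect_identical(cb$n_events[cb$event_type == "SE"], 3L)
  expect_identical(cb$n_genes[cb$event_type == "SE"], 2L)
  dc <- s$direction_counts
  expect_identical(dc$n_up[dc$event_type == "SE"], 3L)
  expect_identical(dc$n_down[dc$event_type == "RI"], 1L)
  expect_identical(sum(s$chromosome_histogram$n_up) + sum(s$chromosome_histogram$n_down),
                   nrow(ev))
  # g2 carries SE and RI -> multi-type gene
  g2 <- s$gene_type_overlap$event_types[s$gene_type_overlap$gene_id == "g2"]
  expect_identical(g2, "RI,SE")
  expect_equal(s$fraction_genes_multi_event, 2 / 3)
  # totals conserved under reordering
  s2 <- summarize_events(ev[rev(seq_len(nrow(ev))), ])
  expect_identical(s2$counts_by_type, s$counts_by_type)
  # empty input -> all-zero summary
  s0 <- summarize_events(ev[0, ])
  expect_true(all(s0$counts_by_type$n_events == 0L))
})

test_that("PSI-expression correlation recovers perfect linearity and flags degenerate input", {
  psi <- matrix(seq(0.1, 1, length.out = 10), nrow = 1,
                dimnames = list("e1", paste0("s", 1:10)))
  expr <- matrix(2 * psi, nrow = 1, dimnames = list("g1", paste0("s", 1:10)))
  map <- data.frame(event_id = "e1", gene_id = "g1")
  res <- psi_expression_correlation(psi, expr, map)
  expect_equal(res$per_event$r, 1, tolerance = 1e-12)
  expect_equal(res$per_event$r_squared, 1, tolerance = 1e-12)
  # constant expression -> r_squared 0
  expr2 <- matrix(5, nrow = 1, ncol = 10, dimnames = list("g1", paste0("s", 1:10)))
  res2 <- psi_expression_correlation(psi, expr2, map)
  expect_identical(res2$per_event$r_squared, 0)
  # zero-variance PSI -> skipped with a reason
  psi3 <- matrix(0.5, nrow = 1, ncol = 10, dimnames = list("e1", paste0("s", 1:10)))
  res3 <- psi_expression_correlation(psi3, expr, map)
  expect_identical(res3$per_event$skipped_reason, "zero-variance PSI")
  # n below the minimum -> skipped
  res4 <- psi_expression_correlation(psi[, 1:2, drop = FALSE],
                                     expr[, 1:2, drop = FALSE], map)
  expect_identical(res4$per_event$skipped_reason, "too few paired observations")
})
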