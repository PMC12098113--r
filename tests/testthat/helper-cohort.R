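# Shared fixtures: simulated cohorts are expensive, so they are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The study-condition cohort: 25 signal + 25 null events per type,
# |deltaPSI| = 0.3, sd = 0.05, 40 old vs 40 young samples, 50% proteomic
# capture with 200 decoys, [ACT]ATATA planted at 3x background.
default_cohort <- function() {
  cached_fixture("default", simulate_cohort(sim_config(seed = 1L)))
}

# Same design with no motif enrichment (fold = 1): the null motif run.
null_motif_cohort <- function() {
  cached_fixture("null_motif",
                 simulate_cohort(sim_config(seed = 11L, motif_enrichment_fold = 1)))
}

# A small cohort for cheap unit-level checks.
small_config <- function(seed = 42L) {
  sim_config(seed = seed, n_chromosomes = 2L, chromosome_length = 60000L,
             n_events_per_type = c(SE = 2L, A5SS = 2L, A3SS = 2L, MXE = 2L, RI = 2L),
             n_null_events_per_type = c(SE = 2L, A5SS = 2L, A3SS = 2L,
                                        MXE = 2L, RI = 2L),
             n_young = 6L, n_old = 6L, n_proteomic_decoys = 20L, n_genes = 22L)
}

small_cohort <- function() cached_fixture("small", simulate_cohort(small_config()))

# Events of the default cohort with the differential-PSI statistics filled.
default_events_tested <- function() {
  cached_fixture("default_tested", add_differential_psi(default_cohort()$events))
}

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

# Minimal stand-in isoform pair for subtraction tests that only need the
# two protein strings.
fake_pair <- function(p_aging, p_other, aging = "inclusion", event_id = "ev1",
                      gene = "GENE1") {
  forms <- list(inclusion = list(protein = if (aging == "inclusion") p_aging else p_other),
                exclusion = list(protein = if (aging == "exclusion") p_aging else p_other))
  structure(list(event_id = event_id, gene_symbol = gene, cds_changed = TRUE,
                 aging_favored = aging, inclusion = forms$inclusion,
                 exclusion = forms$exclusion, frame_effect = "preserving"),
            class = "isoform_pair")
}
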