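# splicepitope

Discovery of candidate neoantigens arising from differential alternative
splicing between two groups of samples — for example old versus young
blood cohorts, where age-shifted splicing can place peptides on the cell
surface that the young proteome never produced.

## The problem and the method

Bulk RNA-seq cohorts are routinely screened for differential splicing with
rMATS, which reports, per event, junction counts, per-sample Percent
Spliced In (Ψ) and a false-discovery rate. `splicepitope` takes the
pipeline from there to candidate MHC class-I neoantigens:

1. **Event filtering.** Parse rMATS junction-count (JC) tables for the
   five canonical event types (SE, A5SS, A3SS, MXE, RI) and keep events
   with FDR < 0.05 and |ΔΨ| > 0.1 (both strict), where
   ΔΨ = mean Ψ(old) − mean Ψ(young). A two-group t-test /
   Wilcoxon statistic with joint Benjamini–Hochberg correction is provided
   for synthetic or pre-computed Ψ matrices.
2. **Isoform surgery.** For each significant event, reconstruct the
   inclusion- and exclusion-form isoforms against the reference genome and
   GTF by adding, deleting or swapping exons, extract both coding
   sequences, and classify the consequence (frame-preserving /
   frame-disrupting / non-coding). The aging-favored form is the inclusion
   form iff ΔΨ > 0.
3. **Peptide subtraction.** Translate both forms, enumerate 9-mers by a
   one-residue sliding window, and keep the k-mers of the aging-favored
   protein that occur neither in the other form nor in a background
   peptide library built from reference (young/middle-aged) transcript
   translations.
4. **Presentation.** Score every candidate against every cohort HLA
   class-I allele through a pluggable percentile-rank predictor (an
   offline NetMHCpan-style table adapter, or a deterministic mock), keep
   ranks strictly below 5%, and aggregate per-allele counts, per-individual
   presented sets, peptide prevalence and the peptides shared by all
   individuals.
5. **Proteomic confirmation.** Flag candidates whose sequence and gene
   symbol exactly match an observed proteomic peptide list.

Event-level analytics from the same screen are included: type/direction/
chromosome summaries, multi-event gene overlap, Ψ–expression OLS
correlation, protein-domain overlap, and RNA-binding-protein motif density
maps (sliding-window coverage of degenerate motifs such as the RBMS3
motif `[ACT]ATATA` in 250 bp intron / 50 bp exon flanks, tested per
position against non-significant background events).

A fully self-contained synthetic-cohort generator (`simulate_cohort()`)
plants events of all five types with controlled group-wise Ψ shifts,
engineered frame-preserving inserts, known novel peptides, HLA genotypes,
a partial proteomic capture and motif-enriched flanks — with
machine-readable ground truth, so the whole pipeline is testable without
any external data.

## Worked example

```r
library(splicepitope)

cfg    <- sim_config(seed = 1)      # 25 signal + 25 null events per type,
cohort <- simulate_cohort(cfg)      # 40 old vs 40 young samples

events <- add_differential_psi(cohort$events)
sig    <- filter_significant(events, fdr_max = 0.05, min_abs_dpsi = 0.1)
#> 125 of 250 events significant

summarize_events(sig)$direction_counts
#>   event_type n_up n_down
#> 1         SE   10     15
#> 2       A5SS   25      0
#> 3       A3SS   25      0
#> 4        MXE   25      0
#> 5         RI   25      0

dc <- discover_candidates(sig, cohort$models, cohort$genome, cohort$background)
#> 3939 candidate 9-mers from 125 events

matched <- match_proteomics(dc$candidates, cohort$observed_peptides)
attr(matched, "n_matched_sequences")
#> 1969 candidates confirmed in the proteomic list

calls <- filter_binders(matched, cohort$genotypes_long, 5, mock_predictor())
cs    <- summarize_cohort(calls, cohort$genotypes_long)
head(cs$per_allele[order(-cs$per_allele$n_bound_peptides), ], 3)
#>       allele n_bound_peptides carrier_rate allele_frequency
#> 5 HLA-B08:01              212        0.425           0.2875
#> 7 HLA-C14:02              209        0.700           0.4375
#> 8 HLA-C07:01              203        0.825           0.5625
```

All 125 planted signal events are recovered (no null event passes the
filter), the 3,939 candidates equal the generator's ground-truth planted
peptides exactly, and the 1,969 proteomic matches are exactly the planted
peptides the generator emitted into the observed list (none of the 200
decoys match). Per-allele detection is reported both as carrier fraction
and allele frequency, since the two denominators are both in use in the
field.

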