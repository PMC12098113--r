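---
title: "Splice-derived neoantigen discovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-derived neoantigen discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`splicepitope` implements a pipeline for finding candidate MHC class-I
neoantigens produced by differential alternative splicing between two
sample groups, together with the event-level analytics that usually
accompany such a screen. This vignette is the package's account of the
method: the model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## The model

A differential-splicing screen (rMATS-style) supplies, per event, the
per-sample Percent Spliced In ($\Psi$, the fraction of a gene's
transcripts using the inclusion form, estimated from junction reads) in
two groups, plus a p-value and FDR. Writing group 1 for the old group,

$$\Delta\Psi = \overline{\Psi}_{\text{old}} - \overline{\Psi}_{\text{young}},$$

an event is *significant* when $\mathrm{FDR} < 0.05$ **and**
$|\Delta\Psi| > 0.1$, both strict; ties are excluded. An event with
$\Delta\Psi > 0.1$ is read as *higher usage of the inclusion form in the
old group*.

For each significant event the *aging-favored* isoform (the inclusion
form iff $\Delta\Psi > 0$) is rebuilt against the reference annotation by
exon surgery:

* **SE** — inclusion keeps the cassette exon, exclusion removes it;
* **RI** — inclusion merges the two flanking exons and the intron into a
  single exon, exclusion keeps them split;
* **MXE** — inclusion carries exon 1 and not exon 2, exclusion the
  converse (exon 1 = the genomically first exon, the rMATS "1st exon");
* **A5SS/A3SS** — inclusion uses the long exon, exclusion the short one.

Both forms keep the reference's annotated CDS bounds. Their spliced CDS
are compared: if they differ, the event is *frame-preserving* when the
length difference is divisible by 3 and *frame-disrupting* otherwise; if
surgery removed the start codon or the CDS, the event is *non-coding* and
excluded from peptide work. Translation uses the standard code, truncates
at the first in-frame stop (no NMD modelling — peptides upstream of a
premature stop are kept), maps codons containing `N` to `X`, and ignores
a trailing partial codon.

Candidate peptides are the 9-mers (one-residue sliding window) of the
aging-favored protein that survive two subtractions: the 9-mer set of the
other form of the *same* event, and a global background library built
from reference ("young/middle-aged") transcript translations. Windows
containing `X` cannot be rank-scored and are dropped (counted in a QC
tally). The window length is configurable (8–11) but defaults to 9, the
canonical MHC class-I length.

Candidates are scored against every distinct HLA class-I allele in the
cohort through a percentile-rank predictor and called binders at
rank < 5% (strict). A peptide is *presented by an individual* iff at
least one of their up-to-six alleles yields a binder call. Cohort
statistics follow: distinct bound peptides per allele, per-individual
presented sets, per-peptide prevalence, the set presented by every
individual, and per-sample locus counts. Because published "detection
rates" are ambiguous between denominators, the per-allele table reports
both the carrier fraction (individuals carrying the allele / cohort size)
and the allele frequency (copies / 2N).

Finally, a candidate is *proteomics-confirmed* when an observed peptide
list contains an entry with an identical sequence **and** an equal gene
symbol (case-insensitive). For full-length short peptides at 100%
identity, exact string matching coincides with a blastp search but is
deterministic, so no aligner is invoked. Isobaric residues (I/L) are
deliberately kept distinct.

## Event-level analytics

* `summarize_events()` counts events and distinct genes per type, splits
  by direction at $|\Delta\Psi| = 0.1$, builds the per-chromosome up/down
  histogram and the per-gene set of event types (UpSet-style input), and
  reports the fraction of genes with two or more events — counted both as
  distinct types per gene and total events per gene, since the two
  conventions differ.
* `psi_expression_correlation()` fits, per event, an ordinary
  least-squares regression of gene expression on $\Psi$ across samples
  (equivalently a Pearson correlation with a slope t-test; $n \ge 3$
  required, zero-variance $\Psi$ skipped), with per-type roll-ups:
  events, events at $p < 0.05$, max and mean $r^2$.
* `overlap_domains()` intersects each event's affected protein interval —
  located from the longest common prefix/suffix of the two CDS and
  converted to residues as $[\lfloor \text{first}/3 \rfloor,
  \lceil \text{last}/3 \rceil)$, with everything downstream affected for
  frameshifts — with protein-domain annotations (a converter from 1-based
  inclusive InterProScan coordinates is provided). Intervals are half-open:
  abutting intervals do not overlap.
* `extract_flanks()` / `compare_profiles()` reimplement the motif-map
  analysis: 250 bp intron and 50 bp exon flanks around each event's
  target region, read 5'→3' on the coding strand; per-position coverage
  by (possibly overlapping) matches of a degenerate motif such as
  `[ACT]ATATA`; 50 bp sliding-window densities; and a per-offset
  two-sided Wilcoxon rank-sum test of significant events against the
  non-significant background. A label-permutation test is available as an
  alternative. Positional p curves are reported raw (no multiple-testing
  correction across offsets, the motif-map convention); a BH-adjusted
  column is optional.

### Flank slots

Motif-map tools differ in how many flank windows they define per event
type. This package uses a deliberately simple four-slot layout applied
uniformly: `upstream_intron` (250 bp 5' of the target region),
`target_exon_5prime` / `target_exon_3prime` (first/last 50 bp of the
target), and `downstream_intron` (250 bp 3'). The target region is the
cassette exon (SE), the first exon (MXE), the long exon (A5SS/A3SS) or
the merged retained-intron exon (RI). Intron slots are clipped at the
recorded flanking exons and chromosome ends; clipped regions are flagged
and, in density profiles, anchored at the exon-proximal end so they
contribute only to offsets they cover.

## The synthetic cohort generator

`simulate_cohort()` builds a toy cohort end to end with ground truth,
emulating a two-group design (old vs young blood samples) with planted
splicing effects. Defaults are the study conditions used throughout the
test suite:

| parameter | default | meaning |
|---|---|---|
| `n_events_per_type` / `n_null_events_per_type` | 25 / 25 | signal and null events per type (250 total) |
| `delta_psi_effect` | 0.3 | true \|ΔΨ\| of signal events |
| `psi_noise_sd` | 0.05 | per-sample Ψ noise (must satisfy ΔΨ > 2·sd) |
| `n_old` / `n_young` | 40 / 40 | group sizes |
| `junction_depth` | 100 | junction reads per event and sample |
| `exon_length` / `intron_length` | 90–150 / 260–400 bp | introns exceed 250 bp so flanks fit unclipped |
| `frame_disrupting_fraction` | 0.2 | signal events per type with non-multiple-of-3 length change |
| `se_negative_fraction` | 0.6 | SE signal events with ΔΨ < 0 |
| `proteomic_capture_fraction` | 0.5 | planted peptides emitted into the observed list (rounded, ties down) |
| `n_proteomic_decoys` | 200 | random 9-mers added to it |
| `motif_enrichment_fold` | 3 | placement rate in up-event flanks over background (1 per 250 bp flank) |

Genes (8–9 exons, alternating strands, non-overlapping, one per event)
carry a CDS that starts with `ATG`, has length divisible by 3 and is
written into the genome as stop-free codons, so reference translations
are clean by construction. Each event targets the fourth internal exon
slot of a distinct transcript. Per-sample Ψ is
clamp(group mean + N(0, sd), 0, 1); junction counts are binomial at the
configured depth with equal form lengths so count-derived Ψ matches the
simulated value.

Design features worth knowing:

* **Null events sit in untranslated regions** (their host genes confine
  the CDS to the first two coding exons). A null event that slipped
  through the significance filter would therefore still contribute zero
  candidate peptides — null leakage and peptide contamination are
  decoupled by construction.
* **Signal-event direction is type-specific.** Peptide-bearing events
  need the aging-favored form to differ from the reference annotation:
  for SE that is the exclusion form (ΔΨ < 0, 60% of SE events), for
  RI/MXE/A5SS/A3SS the inclusion form (ΔΨ > 0). The remaining SE events
  are positive and carry planted motifs instead; their aging-favored form
  is the reference, so they correctly yield no novel peptides.
* **Frame-preserving inserts are engineered, not hoped for.** Retained
  introns and splice-site extensions are written as stop-free codons in
  the inclusion frame (phase-aware at both junctions) and
  rejection-resampled (bounded at 1000 draws) until they contribute at
  least one 9-mer absent from the background library. Frame-disrupting
  events keep random insert sequence; their pre-stop novel 9-mers are
  recorded as truth by the same brute-force subtraction the planted
  peptides use, so ground truth covers *every* signal event.
* **Ground truth is computed independently.** The generator assembles
  isoform sequences by direct exon-interval arithmetic and genome
  slicing — separate code from `apply_event()`/`spliced_cds()` — so
  recovery tests compare two independent constructions.
* **Motif planting avoids corrupting coding sequence.** Placements go
  into the coding-upstream intron flank of the target region, which is
  never exonic in either form for SE, RI, MXE and A5SS. A3SS is excluded
  entirely (its acceptor-side extension occupies exactly that flank), so
  A3SS events carry neither enriched nor background placements and
  target-vs-background comparisons are run on the other four types.
  Up-events receive Poisson(fold × 1) placements per flank, null and
  down-events Poisson(1), each a uniformly drawn concrete realization of
  the degenerate pattern at a uniform offset.
* **Determinism.** Every stage seeds the RNG from `seed` plus a fixed
  stage offset, so a configuration reproduces the cohort byte-for-byte
  and stages can be re-run standalone.

What the generator does **not** emulate: read-level noise (no FASTQ, no
alignment ambiguity), realistic HLA population frequencies (a toy
8-allele pool), transcript-assembly artifacts in the background library
(in a real cohort the young/middle-aged library is built from assembled
transcripts of hundreds of samples; here both collapse into one clean
reference-derived set), mass-spectrum generation (peptide lists only),
overlapping genes, multi-isoform genes, and expression–splicing coupling
(the expression matrix is independent noise, making the correlation
screen a null calibration). Passing tests therefore demonstrate
correctness of the pipeline's logic under clean conditions, not
robustness to the measurement noise of real cohorts.

## Numerical conventions and edge cases

* **Coordinates** are 0-based half-open throughout (the rMATS/BED
  convention); GTF input/output converts at the boundary. A single
  internal convention eliminates a whole class of off-by-one errors.
* **Strictness**: FDR exactly 0.05, |ΔΨ| exactly 0.1 and rank exactly
  5.00 are all excluded.
* **"NA" Ψ entries** are dropped from that sample's vector, never
  imputed; an event with fewer than two usable samples in either group
  gets missing statistics and is excluded from the BH correction, which
  is applied jointly across all five event types (the conservative
  reading for a single pooled significance claim).
* **Degenerate tests**: identical group vectors give p = 1; zero
  variance with different means gives p = 0; Wilcoxon uses the normal
  approximation (`exact = FALSE`) because Ψ ties are common.
* **Transcript matching**: an event applies only to transcripts whose
  flanking exons match exactly; among multiple matches the longest CDS
  wins, ties broken by lexicographic transcript id. Unmatched events are
  skipped with a logged reason.
* **The mock rank predictor** maps each (peptide, allele) pair through
  two polynomial string hashes modulo distinct ~2^31 primes (exact in
  double arithmetic, hence platform-stable) combined into a uniform
  value on (0, 100]. It is calibration plumbing — about 5% of random
  pairs fall below the 5% threshold — not a binding model. Real use
  supplies a saved NetMHCpan-style table through `table_predictor()`,
  which raises an explicit error on unscored pairs rather than
  defaulting silently.

## Problem sizes

The test suite and `scripts/acceptance.R` run the default cohort
(250 events, 260 genes, 4 × 300 kb chromosomes, 80 samples), a second
fold-1 cohort for the motif null run, 10,000 random (peptide, allele)
pairs for rank calibration, and 1,000 null events for the Ψ–expression
calibration; the suite completes in about a minute on one CPU. These
sizes were chosen so every distributional check (≥95% signal recovery,
≤5% null leakage + binomial noise, 5% ± 2% null correlation rate,
binder fraction 5% ± 1%) has comfortable statistical margin.

## Known limitations

Single-isoform surgery (no combinatorial events per transcript), no de
novo ORF calling when the annotated start is lost, no NMD or
proteasomal-cleavage modelling, no immunogenicity beyond presentation
rank, and exact-match-only proteomic confirmation (no spectral FDR).
These mirror the boundaries of the screen the package implements.
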