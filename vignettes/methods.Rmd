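---
title: "Methods: junction-read PSI quantification and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction-read PSI quantification and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agesplice)
```

## Scope and model

`agesplice` implements the computations needed to compare the
prefrontal-cortex (or any bulk-tissue) transcriptomes of two small,
deeply sequenced cohorts — canonically 6 young versus 7 old dogs at
~74 million 124 bp reads per library.  Its core contribution is
cassette-exon percent-spliced-in (PSI) quantification from split reads,
with the surrounding expression, enrichment and qPCR-validation
analyses included so a full cohort comparison can be run and, crucially,
*tested* end to end on synthetic data with known truth.

### PSI from split reads

A cassette exon is an internal exon that mature transcripts either
retain or skip.  Three splice junctions carry the evidence: the two
*inclusion* junctions joining the exon to its upstream and downstream
flanking exons, and the *skip* junction joining the flanking exons
directly.  A split read (one whose CIGAR contains an `N` gap) supports
inclusion when one of its gaps coincides exactly with an inclusion
junction, and skipping when a gap coincides with the skip junction.

Raw counts are not comparable across the two outcomes: an included
transcript exposes **two** junctions to sequencing while a skipped
transcript exposes one, and each junction can be hit by
`read_length − 2·anchor_min + 1` distinct read placements.  We therefore
normalize each count by (number of supporting junctions) × (placements
per junction):

$$\mathrm{IR}_n = \frac{\mathrm{IR}}{2\,P}, \qquad
  \mathrm{ER}_n = \frac{\mathrm{ER}}{P}, \qquad
  P = L - 2a + 1,$$

with $L$ the uniform read length and $a$ the anchor requirement, and
estimate

$$\mathrm{PSI} = \frac{\mathrm{IR}_n}{\mathrm{IR}_n + \mathrm{ER}_n}.$$

With uniform read length the placement factor $P$ cancels inside the
ratio; the junction-count factor 2 does not, and omitting it would bias
PSI downward (an exon present in half the transcripts would be estimated
at 1/3).  When junction coverage for an exon in a sample falls below
`min_junction_reads` raw reads, the PSI is reported as undefined (`NA`)
rather than as a noisy number.

Counting is deliberately exact: junction coordinates must match the
annotated donor/acceptor to the base, with at least `anchor_min` aligned
bases on each side of the gap.  Exact matching keeps the estimator
deterministic and testable; alignment slop around splice sites is a
property of the aligner, not of this quantification, and fuzzy matching
would make inclusion/exclusion assignment ambiguous for nearby events.
A read whose alignment spans both inclusion junctions (possible when the
exon is shorter than the read) counts once.  Only primary, mapped
alignments contribute, each mate independently; no mapping-quality
filter is applied by default.

### Cohort comparison

Per-exon PSI values are averaged within each cohort over the samples
where PSI is defined; exons with fewer than `min_defined_samples`
(default 3) defined values in either cohort are dropped, since a cohort
mean over one or two samples is not a cohort estimate.  The contrast is
`delta_psi = mean(old) − mean(young)`, so positive values mean more
inclusion in the old cohort, and an exon is *flagged* when
`|delta_psi|` strictly exceeds `delta_threshold` (default 0.20 — a
20-percentage-point shift in inclusion).  The strict inequality is a
deliberate tie-break choice at the boundary, exposed in the
configuration.  No formal test accompanies the threshold: at these
cohort sizes a ΔPSI threshold is the established practice, and the
package's simulations quantify its operating characteristics instead
(see below).  Overall concordance between cohorts is summarized by
Spearman's rank correlation of the two cohort-mean vectors.

### Expression summaries

Counts per million are `count / library_size × 1e6`, with library sizes
taken as column sums unless overridden.  A gene is *detected* in a
cohort when its CPM reaches `detect_threshold` (default 0.3, roughly 20
reads at ~70 M depth) in at least one sample of the cohort; the one-
sample rule is the package's reading of "expressed in at least one
sample", and the detection partition (cohort-exclusive vs shared genes)
follows from it.  DEG tables (linear fold change old/young plus
q-value) are categorized with strict `FC > 1.5` for a more-than-1.5-fold
increase, `FC ≤ 0.5` for a half-or-less decrease, and `0.5 < FC < 1.5`
as "small change"; percentage shares are rounded half-up to one decimal,
matching how such tables are conventionally reported (base R's
round-half-even would report 6.25% as 6.2%).

MDS uses classical (Torgerson) scaling of pairwise sample distances.
The default distance is the *leading log fold change*: the
root-mean-square of the `top_n` (default 500) largest absolute log2 CPM
ratios per sample pair, after adding `prior_count = 2` CPM to avoid
log 0 (the edgeR-convention prior).  An alternative `bcv` mode ranks
genes once by log-CPM variance and uses a two-point coefficient-of-
variation proxy per pair; it is an explicit simplification of
dispersion-based (BCV) MDS and is documented as not numerically
identical to edgeR's tagwise version.

### Overrepresentation and qPCR validation

Term enrichment uses the hypergeometric model: `expected =
n_term_in_reference × n_target / n_reference`, `fold = observed /
expected`, with a *two-sided* Fisher exact p-value so both over- and
underrepresentation are reported (published tables of this kind include
folds well below 1), and Benjamini–Hochberg FDR across tested terms.
Terms with fewer than `min_term_size = 2` reference genes are skipped.
The package does not attempt to reproduce any external annotation
service's internally remapped gene totals; observed and expected counts
are taken from the data given to it.

qPCR validation is plain ΔΔCt: replicate wells are averaged per sample
and gene, each sample's target Ct is normalized to a housekeeping gene
(GAPDH by default), cohort mean ΔCt values are differenced and
`FC = 2^(−ΔΔCt)`.  No primer-efficiency correction is applied.
Concordance with sequencing fold changes is Pearson correlation on the
log2 scale — fold changes are ratios, and correlating them linearly
would let a single large fold change dominate.

## The synthetic-data generator

The simulator exists so every downstream stage can be validated against
known truth.  Its defaults are the study conditions the package
targets: 6 + 7 samples, 74 M-read libraries (scaled by `depth_factor`
for bench-size runs), 124 bp reads, and a mean split-read depth of 200
per junction.

*Counts.*  Gene relative abundances are log-normal (sdlog 1.2, a
typical bulk abundance spread), library sizes log-normal with ~17%
coefficient of variation (matching the spread of real per-library
depths), and counts negative-binomial with dispersion 0.1 (BCV ≈ 0.32,
appropriate for outbred individuals; 0 gives Poisson).  A configurable
fraction of genes (default 0.2) receives a planted log2 fold change
drawn Normal(0, 0.8) applied to the old cohort.

*Splice reads.*  For each sample and planted cassette event with true
inclusion $\psi$, the generator emits per-junction Poisson counts:
each inclusion junction at rate $\lambda\psi$ and the skip junction at
$\lambda(1-\psi)$, where $\lambda$ is the configured junction depth.
This mirrors the physical process — an included transcript yields
evidence at *both* of its junctions — and is exactly the model under
which the two-junction normalization above recovers $\psi$.  The gap
position within each read is uniform subject to the anchor requirement,
so anchor filtering is exercised; reads overrunning a short exon
continue across the second inclusion junction as three-block
alignments.  Reads are emitted only over junctions (no exon-body
background) so the emitted counts are themselves the exact truth for
the counter; gene models used for simulation keep one cassette event
per gene so no two events share a junction.

What the simulator does **not** emulate: sequencing errors and quality
strings, paired-end fragment geometry, alignment ambiguity and soft
clipping around splice sites, novel (unannotated) junctions, and
intron-retention or alternative-site events.  Passing the recovery
tests therefore demonstrates the correctness of the counting and
estimation machinery under clean alignments — not robustness to aligner
artifacts on real data.

## Verification strategy and problem sizes

The test suite runs three kinds of checks, sized to finish in a few
minutes on one CPU:

* **Oracle equivalence** — CIGAR block extraction against a per-base
  reference-cursor simulation on 1,000 random CIGARs; Fisher p-values
  against exhaustive hypergeometric enumeration on tables with up to 60
  genes; classical MDS against a hand-built 3–4–5 triangle (exact to
  1e-9); emitted simulator counts against `count_junction_reads`
  output, which must agree exactly.
* **Parameter recovery** — at per-junction depth 200 over 13 samples,
  the PSI estimate's mean absolute error across 150 events stays below
  0.05; with no planted difference, fewer than 1% of exons are flagged
  at the 0.20 threshold; with a planted |ΔPSI| = 0.4 across 30 events,
  more than 95% are flagged.
* **Worked identities** — the PSI anchor points (no exclusion evidence
  → 1; 1:9 normalized evidence → 0.1), published observed/expected
  fold-enrichment pairs, fold-change category shares, cohort body-mass
  summaries, and the CPM column-sum identity.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GTF (1-based inclusive)
  and SAM (1-based) conversions happen only in readers/writers, which
  eliminates off-by-one ambiguity in junction matching.  Junctions are
  stored in genomic (forward) orientation regardless of strand.
* `anchor_min = 8` bp and `min_junction_reads = 10` are pragmatic
  defaults in line with common splice-junction practice; both are
  exposed in every relevant function.
* Candidate cassette exons are enumerated from annotated transcripts
  only (every exon that is internal in at least one transcript);
  novel-junction discovery is out of scope.  The same exon with
  different flanking contexts in different transcripts yields distinct
  events.
* Cohort labels are fixed as `young`/`old` with Δ = old − young;
  swapping labels flips the sign of Δ but not the flagged set.
* `fisher.test` can overshoot p = 1 by floating error; p-values are
  clamped before FDR adjustment.
* Determinism: every stochastic component takes an integer seed;
  per-sample draws come from one seeded stream in fixed sample order,
  so outputs are byte-identical across reruns with the same seed.

## Known limitations

* PSI is estimated from junction reads only; an optional exon-body mode
  is intentionally not the default because body reads require an
  exon-length normalization whose exact published form varies between
  protocols.
* The ΔPSI threshold is a screen, not a test; no per-exon significance
  is attached.
* The `bcv` MDS mode is a proxy, not a negative-binomial dispersion
  estimate.
* The SAM reader handles plain text SAM (the format the simulator
  emits); BAM inputs should be converted upstream.
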