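# agesplice

Tools for comparing bulk RNA-seq transcriptomes between two age cohorts,
built around junction-read quantification of cassette-exon inclusion.
The package targets the kind of study design common in companion-animal
aging genomics — a small young cohort versus a small old cohort (6 vs 7
individuals by default), deeply sequenced (~74 M reads/library, ~124 bp
reads) — and covers the downstream analyses such a study needs:

* **PSI quantification** — percent spliced in per cassette exon per
  sample, from split reads in SAM alignments;
* **differential splicing** — cohort-averaged PSI, ΔPSI flagging and
  rank concordance between cohorts;
* **expression summaries** — CPM, detection/cohort-exclusive gene
  logic, fold-change categorization of DEG tables, blood-marker
  screening, cohort metadata statistics, and MDS of expression profiles;
* **overrepresentation testing** — fold enrichment with Fisher exact
  p-values and Benjamini–Hochberg FDR;
* **qPCR cross-validation** — ΔΔCt relative quantification and
  platform concordance;
* **a splice-aware simulator** — synthetic cohorts with known planted
  fold changes and exon inclusion fractions, so the entire pipeline is
  testable end to end without any sequencing data.

## The statistic at the core

For a cassette exon *i*, split reads crossing either of its two flanking
(inclusion) junctions support inclusion, and split reads crossing the
junction that joins the flanking exons directly support skipping.  With
raw counts IR and ER normalized for the number of supporting junctions
and the number of read placements per junction (read length and anchor
requirement), the percent spliced in is

```
PSI_i = IR_i,n / (IR_i,n + ER_i,n)
```

PSI = 1 means the exon is included in every transcript sequenced; 0.1
means it is included in 10% of them.  Cohorts are compared on
cohort-averaged PSI: exons whose average inclusion differs by more than
20 percentage points (|ΔPSI| > 0.20, strict) between the cohorts are
flagged as divergent.

## Worked example

Simulate a 6-vs-7 cohort with 20 cassette events — 15 stable at
PSI 0.5, 5 shifting from 0.3 (young) to 0.7 (old) — then quantify and
compare:

```r
library(agesplice)
library(dplyr)

models  <- simulate_gene_models(20, seed = 42)
catalog <- cassette_exon_catalog(models)
truth   <- cassette_truth(catalog, 20,
                          psi_young = c(rep(0.5, 15), rep(0.3, 5)),
                          psi_old   = c(rep(0.5, 15), rep(0.7, 5)),
                          seed = 42)
cfg <- sim_config(seed = 42, junction_depth_mean = 200)
sim <- simulate_splice_reads(cfg, models, truth)

groups <- tibble::tibble(sample_id = names(sim$sam_paths),
                         cohort = rep(c("young", "old"), c(6, 7)))

pm  <- psi_matrix(sim$sam_paths, semi_join(catalog, truth, by = "exon_key"))
cmp <- compare_splicing(pm, groups,
                        gene_map = catalog[c("exon_key", "gene_id")])
glance(cmp)
#> # A tibble: 1 × 5
#>   n_exons n_flagged_exons n_flagged_genes    rho delta_threshold
#>     <int>           <int>           <int>  <dbl>           <dbl>
#> 1      20               5               5 -0.582             0.2

head(tidy(cmp), 3)
#> # A tibble: 3 × 8
#>   exon_key   mean_psi_old mean_psi_young n_old n_young delta_psi flagged gene_id
#>   <chr>             <dbl>          <dbl> <int>   <int>     <dbl> <lgl>   <chr>
#> 1 chr1:1240…        0.718          0.300     7       6     0.419 TRUE    sgene_…
#> 2 chr1:1321…        0.706          0.289     7       6     0.417 TRUE    sgene_…
#> 3 chr1:1493…        0.699          0.298     7       6     0.401 TRUE    sgene_…
```

Exactly the 5 planted events are flagged (no false positives among the
15 stable exons), each with an estimated ΔPSI close to the planted 0.4;
the gene rollup resolves them to 5 distinct genes.  `autoplot(cmp)`
draws the young-vs-old PSI scatter with divergent exons in red.  The
negative `rho` here simply reflects that 15 of the 20 simulated exons
share the same true PSI, so their rank order across cohorts is noise —
on genome-scale data with a spread of inclusion levels the rank
concordance is close to 1.

The expression side works the same way from a count table:

```r
sim_counts <- simulate_counts(sim_config(seed = 1, depth_factor = 1e-3))
cpm_tbl <- cpm(sim_counts$counts)
mds <- mds_embedding(cpm_tbl, top_n = 500, groups = sim_counts$groups)
autoplot(mds)
```

A thin command-line front end (`inst/scripts/agesplice`) exposes the
same stages as subcommands (`simulate`, `psi`, `diffsplice`,
`summarize`, `enrich`, `qpcr`, `all`) over a flat key-value config file;
see `?run_pipeline`.

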