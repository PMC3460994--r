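# hictrans

Do chromosomal translocation partners sit close together in the normal
nucleus? `hictrans` implements the statistical machinery for answering that
question from trans-chromosomal Hi-C contact maps: contact-map
normalization and scoring, cytogenetic catalog parsing, permutation null
models for region pairs, A/B compartment assignment, and read-level
fine-mapping of existing rearrangements. It is aimed at researchers in
genome organization and cancer genomics who have binned Hi-C data and a
catalog of translocations (karyotype notation such as `t(9;22)(q34;q11)`,
or sequencing breakpoints) and want calibrated evidence for or against
contact-first translocation formation.

## The statistics at the core

* **Hi-C score.** For each trans 1-Mb bin pair, the observed count
  *O(i,j)* is compared to a per-bin expected model *E(i,j) = mᵢmⱼ/T*
  (marginal product per chromosome pair, optionally smoothed), and scored
  as *S(i,j) = log₂((O + c)/(E + c))* with pseudocount *c* = 1. Bins over
  centromeres or with zero coverage are masked throughout.
* **Proximity score.** A translocation's two partner regions, snapped to
  whole bins, define a block of bin pairs; the proximity score is the mean
  of *S* over the unmasked block.
* **Permutation tests.** Four null constructions preserve chromosome
  pairings and region sizes (re-place both regions; fix one and re-place
  the partner on its own chromosome / on any other chromosome / from the
  catalog's own partner pool), with a validity rule that rejects regions
  that are at least half masked, and an optional same-compartment
  constraint. P-values use the add-one estimator (never zero, ties count
  against significance); per-pair results are Benjamini–Hochberg
  corrected; group results report permutation, Student's t, and Wilcoxon
  rank-sum p-values.
* **Compartments.** PC1 of the Pearson correlation between a chromosome's
  trans score rows, sign-anchored to gene content; positive = open (A).
* **Corner signature.** An unbalanced translocation concentrates trans
  reads in one quadrant decaying from the breakpoint; the fine-mapper
  zooms 1 Mb → 3 Mb window → 50 kb corner → 1 kb, calling a corner only if
  its quadrant holds ≥ 60% of window reads and both marginal profiles
  decay (Spearman ≤ −0.5).

A seeded synthetic-data generator (`simulate_study()`) produces every input
the pipeline reads — contact triplets, cytoband tables, gene BED,
karyotype and breakpoint catalogs, read pairs — under the generative model
the methods assume, so the whole pipeline is testable without downloads.

## Worked example

Simulate a study whose catalog mixes 10 pairs drawn from three-fold
contact hotspots with 8 random band pairs, then run the full analysis
(mask → expected model → scores → compartments → proximity → permutation
tests) with null construction 1 and 200 permutations:

```r
library(hictrans)
library(dplyr)

hs <- tibble::tibble(
  chrom_a = "chr1", band_a = c("q22", "q24", "p22"),
  chrom_b = "chr2", band_b = c("p22", "q23", "q22"), fold = 3
)
cfg <- sim_config(n_chrom = 2, chrom_length = 60e6, lambda = 30,
                  hotspots = hs, n_true = 10, n_null = 8, seed = 71)
study <- simulate_study(cfg)
pairs <- parse_karyotype_catalog(study$catalog, study$bands, study$assembly)
out <- analyze_catalog(pairs, study$map, study$bands, study$genes,
                       perm_config(method = 1, n_perms = 200, seed = 5))
glance(out$group)
#> # A tibble: 1 × 9
#>   n_pairs observed_mean null_mean p_value t_test_p rank_sum_p method n_perms
#>     <int>         <dbl>     <dbl>   <dbl>    <dbl>      <dbl>  <int>   <int>
#> 1      10         0.344    -0.177 0.00498   0.0403     0.0148      1     200
```

The 10 unique catalog pairs average a Hi-C score of 0.344 (about 1.27-fold
observed/expected enrichment), while none of the 200 permuted catalogs
reaches that mean — the add-one permutation p-value is 1/201 ≈ 0.005, and
the rank-sum comparison against the pooled permuted scores agrees
(p ≈ 0.015), so the group signal is not driven by a single outlier. The
per-pair view shows the planted hotspot pairs at the top:

```r
out$proximity |> arrange(desc(proximity_score)) |>
  select(source_label, proximity_score, n_bin_pairs_used) |> head(4)
#> # A tibble: 4 × 3
#>   source_label        proximity_score n_bin_pairs_used
#>   <chr>                         <dbl>            <int>
#> 1 t(1;2)(q28.1;q28.1)           1.28                 1
#> 2 t(1;2)(p22;q22)               1.16                10
#> 3 t(1;2)(q22;p22)               0.832               25
#> 4 t(1;2)(p28.2;q25)             0.740                3
```

`proximity_score` is the mean log₂ observed/expected contact over the
band-pair block (1.16 ≈ 2.2-fold enrichment over the whole 10-bin block),
and `n_bin_pairs_used` counts the unmasked bin pairs behind each mean.
`out$summary` collects the dataset-level table (mean observed and permuted
scores, the three p-values, the number of individually significant pairs
at BH q < 0.05, unique pair count, and genome/trans-bin coverage), and
`autoplot(out$group)` draws the permutation null histogram with the
observed mean marked.

Fine-mapping works from read-level data:

```r
reads <- dplyr::bind_rows(
  simulate_translocation_reads("chr1", 12.345e6, "chr2", 23.456e6,
                               orientation = "+-", n_reads = 2000),
  simulate_uniform_reads(study$assembly, "chr1", "chr2", 500)
)
finemap_breakpoints(reads, study$scheme)
```

which returns a BEDPE-style table whose single row localizes the planted
breakpoint to its 50-kb corner bin (`chr1:12,300,000`–`12,350,000` ×
`chr2:23,450,000`–`23,500,000`) with orientation `+-` and a signature
score near 1.

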