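---
title: "Methods: testing spatial proximity of translocation partners with trans Hi-C maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing spatial proximity of translocation partners with trans Hi-C maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hictrans)
library(dplyr)
```

## The question and the model

Chromosomal translocations join segments of two different chromosomes. Under
the contact-first model, loci that are spatially proximal in the normal
nucleus are more likely to become translocation partners when double-strand
breaks on both are repaired illegitimately. `hictrans` tests this model:
given a binned trans-chromosomal Hi-C contact map and a catalog of disease
translocations (reported either as cytogenetic band pairs or as sequencing
breakpoints), it asks whether the partner regions show more contact than
matched random regions.

The pipeline has four statistical components, each usable on its own:

1. **Contact scoring.** Observed counts $O(i,j)$ for 1-Mb bin pairs are
   compared to a per-bin expected model, and each trans bin pair gets the
   score $S(i,j) = \log_2\frac{O(i,j) + c}{E(i,j) + c}$.
2. **Proximity scoring.** A translocation with partner regions $A$ and $B$
   (multi-megabase bands, snapped outward to whole bins) gets the mean of
   $S$ over the full block $A \times B$ of unmasked bin pairs.
3. **Permutation testing.** Catalogs and individual pairs are tested
   against four null constructions that preserve chromosome pairings and
   region sizes, optionally constrained to the same chromatin compartment.
4. **Fine-mapping.** Where a translocation already exists in the assayed
   cells, its unbalanced fusion leaves a one-quadrant "corner" of trans
   signal; a hierarchical zoom (1 Mb candidate bin, 3 Mb read window,
   50 kb corner, optional 1 kb refinement) localizes the breakpoint.

## Expected counts and the score

The expected model is a *marginal product* per chromosome pair: with
unmasked marginals $m_i = \sum_j O(i,j)$ and block total $T$,
$E(i,j) = m_i m_j / T$. This absorbs any multiplicative per-bin factor —
coverage, mappability, restriction-site density — and conserves the block
total exactly ($\sum E = \sum T$ by construction; tested to $10^{-9}$
relative). It deliberately replaces the fragment-level probabilistic bias
model used on the original public maps, which needs fragment-level inputs
this package does not consume; an iterative marginal-rebalancing variant
(10 iterations, tolerance $10^{-6}$) is available behind a flag for
stronger bias removal. A linear smoothing filter (window of 3 bins by
default, applied to $E$ only, then renormalized per chromosome pair)
matches the smoothing the original normalization describes; window 1
disables it.

**Pseudocount.** Zero-count bins would send a plain log ratio to
$-\infty$. The default $c = 1$ read implements the variance-stabilizing
intent of the log transform; $c = 0$ is allowed only when every scored bin
has a positive count. The pseudocount shrinks low-coverage scores toward
zero, which is conservative for proximity testing.

**Masking.** Bins overlapping centromeric (`acen`) bands and bins with zero
total coverage across the dataset carry no score, never enter marginals,
and are excluded (but counted) from every block mean.

## Permutation nulls

Per pair, the statistic (proximity score by default; gene content or
compartment score for the feature analyses) is compared against
`n_perms` randomized versions of the pair:

* **Method 1** re-places both regions uniformly on their own chromosomes —
  controls for systematic chromosome-pair association.
* **Method 2** fixes one region and re-places the partner on the partner's
  own chromosome — controls for regions that interact broadly on one
  chromosome.
* **Method 3** fixes one region and re-places the partner uniformly over
  every placement on any other chromosome.
* **Method 4** fixes one region and draws the partner from the catalog's
  own set of partner regions on other chromosomes, keeping the drawn
  region's size.

A candidate region is rejected and redrawn while at least half of its bins
(configurable `validity_threshold`) are masked; rejection sampling keeps
draws uniform over the valid placements (verified against exhaustive
enumeration on maskable toy genomes). P-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perms}} + 1)$ —
never exactly zero, with ties counting against significance. Group tests
permute every pair independently within each replicate and compare the
observed catalog mean against the replicate means; Student's t and
Wilcoxon rank-sum p-values between observed and pooled permuted statistics
are reported alongside to flag outlier-driven results. Per-pair p-values
are corrected with Benjamini–Hochberg, and pairs are flagged at
$q < 0.05$.

**Which side is fixed.** For Methods 2–4 the fixed partner is chosen
uniformly at random *once per pair* (seeded), not independently per draw.
This is deliberate: the observed statistic is exchangeable with draws that
re-randomize a fixed side, but not with a mixture of "fix A" and "fix B"
draws once scores retain any row or column structure, and the mixture
measurably distorts the null calibration. With per-pair fixing, per-pair
p-values on null catalogs are uniform (Kolmogorov–Smirnov distance
below 0.05 across 2,000 pairs for all four methods, with and without
compartment control — the calibration the test suite re-runs).

**Compartment control.** When enabled, candidates must additionally have a
regional compartment score of the same sign as the region they replace
(sign zero counts as open, consistently everywhere). The original analysis
applies this to Methods 1–3; this package also applies it to Method 4 by
filtering the partner pool to same-sign entries, so all four methods can be
run under the same control. A region whose compartment score is undefined
(no scored bins) is left unconstrained.

## Compartments

Per chromosome, the matrix of its unmasked bins against all unmasked bins
on other chromosomes is assembled from $S$, columns are centered, and PC1
of the Pearson correlation matrix between bin rows is the compartment
profile (unit norm; sign oriented so it correlates non-negatively with a
reference track, gene content per bin by default). Positive values are the
open (A) compartment. Column centering matters: after smoothing, the
expected model no longer cancels partner-bin effects exactly, and that
shared residual otherwise inflates all row–row correlations uniformly,
letting the common component displace the compartment contrast whenever A
and B are unbalanced. Centering removes exactly that component and leaves
the hand-derivable two-block case unchanged. Trans rows (rather than cis
maps) are used because the package's data model is trans-only and trans
correlation recovers compartments; a cis-based variant is out of scope.
Region compartment scores are plain means of PC1 over overlapping scored
bins, with "no scored bin" kept distinct from zero.

## Fine-mapping and the corner signature

An unbalanced translocation turns cis contact decay into a trans quadrant:
reads accumulate on one side of the breakpoint on both chromosomes, peaking
at the corner. The detector takes the count-argmax 50-kb bin of the 3-Mb
window as the candidate corner and, for each of the four orientations
(`++`, `+-`, `-+`, `--`; `+` opens toward increasing coordinates), computes
the fraction of window reads in the quadrant the orientation opens from
that corner (corner bin inclusive). The winning orientation is called only
if that fraction reaches 0.6 *and* both marginal read profiles decay away
from the corner (Spearman correlation with distance $\le -0.5$). The
fraction is 0.25 for uniform reads from a central corner and about 0.5 for
a balanced translocation's two opposite quadrants, so the 0.6 bar separates
the unbalanced signature from both; because the corner is an argmax, a
uniform window can place it near a window edge and open a large quadrant —
those windows are rejected by the decay gate, not the fraction. Candidate
chromosome pairs come from a genome scan that flags a pair's maximal
unmasked bin when it exceeds the pair mean by $z = 8$ standard deviations;
refinement to 1 kb is attempted when the corner bin holds at least 20
reads. All thresholds are `finemap_config()` knobs; the defaults hold the
recovery and false-positive rates the test suite measures (exact 50-kb
corner and orientation on planted signals, no flags on background-only
maps).

## The synthetic generator

`sim_config()`/`simulate_study()` generate every input format the package
reads, under the data model the analysis assumes:

* trans counts $O(i,j) \sim \mathrm{Poisson}(\lambda\, b_i b_j\,
  m(l_i, l_j)\, f(i,j))$ with log-normal per-bin biases $b$
  ($\sigma = 0.3$ by default), block-structured compartment labels $l$
  (geometric block lengths, mean 10 bins) with multipliers
  $m_{AA} = 1.4$, $m_{BB} = 1.2$, $m_{AB} = 0.7$ (both homotypic contacts
  enriched, chosen so compartment recovery is comfortably testable), and
  hotspot folds $f$ over configured band-pair blocks;
* cytoband tables with one single-bin `acen` band per chromosome and
  alternating named p/q bands (some split into sub-bands to exercise
  prefix matching);
* gene intervals covering 50% of A bins and 10% of B bins, anchoring the
  PC1 sign;
* catalogs sampled from hotspot band pairs (`n_true`) and random
  inter-chromosomal band pairs (`n_null`), serialized both as karyotype
  notation and as breakpoint records;
* translocation reads from the corner $(x_0, y_0)$ with summed distance
  $s = d_1 + d_2$ following the truncated power law
  $f(s) \propto (s + \delta)^{-\alpha}$ on $[0, 1.4\,\mathrm{Mb}]$
  (inverse-CDF sampling, uniform split between the chromosomes). The
  default $\alpha = 1$ is the classic $\sim s^{-1}$ cis contact decay an
  unbalanced fusion converts into trans signal; $\delta = 1$ kb avoids the
  singularity.

What the generator does *not* emulate: restriction-fragment granularity
(reads are position-continuous, so resolution limits from fragment density
are not modeled), cis maps and their distance decay, copy-number structure,
and non-multiplicative biases. Passing tests therefore demonstrate that
the estimators are correct and calibrated under the stated generative
model, not that real libraries satisfy that model.

## Numerical choices

* Coordinates are 0-based half-open everywhere; regions snap outward to
  whole bins before bin-level work; canonical pair order is lower
  chromosome index first.
* Block means are computed from padded 2-D prefix-sum tables (eight
  lookups per block regardless of size), which is what makes
  per-pair-times-per-draw permutation work affordable in plain R.
  Exceedance comparisons subtract a $10^{-9}$ relative tolerance so a
  genuine tie (a draw re-hitting the observed placement) counts against
  significance regardless of floating-point summation order.
* The eigendecomposition uses the standard symmetric solver; constant bin
  rows are dropped with a warning before correlation, and an all-constant
  chromosome is an error.
* Ties in argmax searches (maximal bin, corner bin, 1-kb refinement) break
  to the lowest `(bin1, bin2)` index.
* Band prefix matching requires the next character to be `.` or the label
  end, so `q1` never matches `q11`; whole-arm records are exactly `p` or
  `q`; 3-way records decompose into their three 2-way pairs and anything
  beyond 3 partners is rejected with a reason code.
* Dataset summaries use unique region pairs; the 95% interval is the
  normal approximation $\bar{x} \pm 1.96\, s/\sqrt{n}$ (the source tables
  state a confidence interval without naming a construction).
* The recurrence analysis reports Spearman correlations and, for the
  p-value-versus-count relation, a regression-slope t-test on ranks; the
  upstream description does not name its exact test, so the choice is
  flagged here.

## Problem sizes in the tests

The test suite and `scripts/acceptance.R` run entirely on synthetic data at
sizes chosen to finish quickly on one CPU: calibration pools 2,001 null
pairs over three 4-chromosome studies (100 bins per chromosome, 200
permutations per test) — pooling across maps keeps the KS statistic a
measure of calibration rather than of the dependence among pairs sharing
one map's fluctuations; power uses 20 studies of 50 planted pairs at 1,000
permutations; enumeration checks use 6-bin toy chromosomes where all 36
placements can be listed; fine-mapping recovery uses 100 planted windows of
2,000 reads and 100 background maps. A full-scale run on real inputs
(thousands of bins, catalogs of ~1,500 rearrangements) is the same code on
larger matrices.

## Limitations

* The marginal-product expected model corrects multiplicative per-bin
  biases only; fragment-level effects and long-range cis structure are out
  of scope.
* Compartment calling is trans-based and two-state; sub-compartments and
  eigenvectors beyond PC1 are not computed.
* The fine-mapper targets unbalanced translocations; balanced events
  (two opposite corners) are deliberately not called.
* Permutation draws are independent across pairs within a replicate; no
  collision avoidance or spatial-autocorrelation-preserving rotation is
  attempted.

## A minimal run

```{r example}
hs <- tibble::tibble(
  chrom_a = "chr1", band_a = c("q22", "q24", "p22"),
  chrom_b = "chr2", band_b = c("p22", "q23", "q22"), fold = 3
)
cfg <- sim_config(
  n_chrom = 2, chrom_length = 60e6, lambda = 30,
  hotspots = hs, n_true = 10, n_null = 8, seed = 71
)
study <- simulate_study(cfg)
pairs <- parse_karyotype_catalog(study$catalog, study$bands, study$assembly)
out <- analyze_catalog(
  pairs, study$map, study$bands, study$genes,
  perm_config(method = 1, n_perms = 200, seed = 5)
)
glance(out$group)
out$summary |> select(mean_score, mean_permuted, permutation_p, n_individual_significant)
```

```{r plot, fig.width = 6, fig.height = 3.5}
autoplot(out$group)
```
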