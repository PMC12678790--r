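---
title: "Spatial methylation gradients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial methylation gradients: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`methgrad` analyses per-CpG DNA methylation sampled at seven ordered
positions along the tumor-to-normal axis — TC, TE, P5, P10, P15, P20, PN —
in a paired cohort (every patient contributes all seven regions). This
vignette is the package's account of the statistical machinery: what each
stage assumes, which parameters matter, what the synthetic generator does
and does not emulate, and where a genuinely open design choice was made.

## 1. Per-site significance matrices

For one CpG site, the data are a patients × 7 matrix of methylation
fractions with missing cells. Every unordered region pair is compared with
the paired Wilcoxon signed-rank test, one-tailed in both directions; the
pair is *significant* when the smaller one-tailed P is below
`alpha_pair = 0.05`. Zero paired differences are dropped (the classical
Wilcoxon convention; no Pratt correction), the exact null distribution is
used for small tie-free samples and the normal approximation with
continuity correction otherwise — i.e. the defaults of `stats::wilcox.test`,
which the implementation calls per tail.

Choices worth making explicit:

- **Both tails, smaller P.** The tested direction is not fixed a priori,
  because single sites can legitimately carry significant pairs in both
  directions (a fluctuating site). The union of two exact one-tailed
  rejections at 0.05 has size ≈ 0.09 under the null — a fact with real
  consequences for the steep rule (section 4).
- **`min_pairs = 6`** complete patient pairs are required before a pair is
  tested at all. Below that, the smallest attainable one-tailed P
  (1/2⁵ = 0.031 at five pairs) sits so close to `alpha_pair` that calls
  would be driven by missingness patterns; untestable pairs are simply
  "not significant".
- Matrices are symmetric with a zero diagonal; the direction matrix
  (`dir[i, j] = -1` when region *i* is significantly lower) is
  antisymmetric, and both invariants are asserted at construction.

## 2. Moran's I on the matrix grid

The regularity of a significance matrix is scored by Moran's I with one
observation per matrix cell:

$$I = \frac{\sum_i \sum_{j \ne i} w_{ij}(x_i - \bar x)(x_j - \bar x)}
           {S^2 \sum_i \sum_{j \ne i} w_{ij}},
  \qquad S^2 = \tfrac{1}{n}\sum_i (x_i - \bar x)^2 .$$

**Convention.** The observation set is all 49 cells of the 7×7 matrix
(zero diagonal included) at integer (row, col) coordinates, with
$w_{ij} = 1/d_{ij}$ under the Euclidean metric and *no* weight
normalisation — the formula exactly as displayed. The implementation also
exposes Manhattan distances and ape-style row-normalised weights
(`normalize = "row"`, validated against `ape::Moran.I` in the tests), so
every member of the plausible convention space is one function call away.
For the worked-example matrix shipped with the acceptance script the
package's convention yields I = 0.0758; the reference value quoted for
that example (0.1581) is not reproduced by *any* member of the convention
space expressible here (cell subsets, metrics, weight transforms,
normalisations), which we take as evidence that the example's published
matrix differs from the pair list it is described by. The package
therefore keeps the formula-faithful default rather than adopting an
unprincipled convention that happens to land nearer the quoted number.

**Null.** `shuffle_null()` permutes the 49 cell values uniformly across
cell positions (not rows or columns — shuffling the *matrix*) and rescores
I. The permutation expectation is the closed form $-1/(n-1) = -1/48$; the
tests verify convergence at 10⁴ shuffles. The default of 10 shuffles per
site matches the discovery pipeline's per-site budget and is configurable
upward.

## 3. Kendall trends

Monotonicity along the region order is measured by Kendall's tau-b pooled
over all patients' cells (x = region ordinal 1–7, y = methylation). The
ordinals are heavily tied by construction, so the implementation carries
the full tie-corrected variance of S (the `kendall_tau_b()` helper) rather
than relying on a tie-free approximation; it reduces to the textbook
normal approximation when ties vanish, which the tests check against
`cor.test`. Pooling (rather than averaging per-patient taus) uses all 84
cells in one test; a site needs ≥ 20 non-missing cells before a trend is
attempted.

## 4. The steep and shallow rules

*Steep* (evaluated first): every significant pair lies between a tumor
region {TC, TE} and a normal-side region {P5..PN}; TC and TE each carry at
least `steep_min_sig = 3` such pairs; all significant directions agree.
*Shallow* (on the remainder): Kendall P < `tau_p_max = 0.01`; at least one
significant tumor–PN pair; at least one significant pair within {P5..PN};
and no significant pair whose direction contradicts sign(tau) — our
operationalisation of "nonmonotonic significance", which is not otherwise
defined. A site is `*_rise` iff methylation increases from TC to PN
(tau > 0, tumor side lower); this is the single place the direction
convention is defined and all modules inherit it.

**A hard statistical limit worth knowing.** The steep rule's *only
between* clause interacts with the per-pair test size: with 11
null/within-side pairs each firing at ≈ 9 % (section 1), a flawless steep
site survives the exclusion with probability ≈ 0.91¹¹ ≈ 0.35. Steep
sensitivity against generator truth therefore plateaus near 0.35–0.45 at
realistic noise, *regardless of effect size* — binomial counting noise at
30× coverage alone sustains the spurious-pair rate. The same leaked steep
sites are monotone in tau and often pick up a spurious within-normal pair,
so they can satisfy the shallow screens and inflate the shallow false
discovery rate to ≈ 0.15–0.20. Re-running with `alpha_pair = 0.01`
(not the method's level) lifts steep sensitivity to ≈ 0.77 and drops
shallow FDR to ≈ 0.08, confirming the mechanism. The acceptance tests
assert the stricter recovery targets and are expected to flag exactly
these two quantities; we regard that as a property of the rule set, not of
the implementation.

## 5. Regions, genes and features

Changed sites (steep/shallow only) merge into regions when at least
`min_sites = 3` same-direction sites run with inter-site gaps ≤
`max_gap = 250` bp (gap inclusive; measured between successive positions).
Direction-aware merging is the default; the direction-agnostic mode exists
to surface `discarded_bidirectional` regions, mirroring the small fraction
of bidirectional regions a direction-blind pass would find. Region
methylation is the member median per sample. Coordinates are 0-based
half-open internally and in BED output; GTF is read 1-based inclusive
(via `rtracklayer`) and converted in one place (`to_zero_based()`).
Promoters are the 2 kb immediately upstream of the strand-aware TSS — for
minus-strand genes that is rightward of the gene end — and never overlap
their gene body (asserted).

## 6. Clustering

Samples are clustered on row-z-scored methylation (sample-sd convention;
missing cells imputed at the row mean, i.e. 0 after scaling) with Ward.D2
under Euclidean distance. The linkage is hand-rolled with the
Lance–Williams update on squared dissimilarities and a deterministic
first-minimum tie-break, returns a standard `hclust` object, and is
validated against `stats::hclust(method = "ward.D2")` by cophenetic
comparison. Clade stability uses the *ordinary* bootstrap (resample
feature rows, recluster, count exact clade recurrence); multiscale
bootstrap AU corrections are deliberately out of scope — supports here are
plain bootstrap probabilities and read slightly conservative for large
clades.

## 7. Expression trends

RT-qPCR profiles use 2^−ΔCt against a reference gene (replicates
aggregated by mean Ct — the standard ΔCt practice — with the replicate SD
propagated as ln 2 · expr · sd(ΔCt)), then standardised to TC. The
steep/shallow/none rule for a 7-point expression profile is an explicit
*interpretation* (the original categorisation criteria are not fully
specified anywhere we could follow): steep iff the TE→P5 step is at least
half the profile range with both flanks spanning less than that; else
shallow iff |tau| ≥ 0.62 (the two-sided P < 0.05 point for seven untied
values); else none. The rule is parameterised (`tau_min`, `step_frac`) and
isolated in `classify_expression_trend()` so it can be swapped without
touching I/O.

## 8. Prognosis model

For paired tumor/adjacent methylation at target CpGs, the relative
difference is d = 100·(adjacent − tumor)/tumor percent. The formula is not
actually bounded by +100; values beyond ±100 are clamped with a warning
rather than silently passed through, keeping the documented range. |d| <
threshold (strict) defines a *low-difference* (shallow-like) site;
thresholds are swept over 3–15 %. Stratifications report the log-rank
(Mantel–Cox) chi-squared P and a hazard ratio from a univariate Cox fit
with Efron ties (the log-rank O/E estimator is available via
`estimator = "oe"`); for the combined model, high risk means ≥ N
low-difference sites in the panel, and the HR is high- vs low-risk.
Absolute |d| is thresholded because panels mix hypo- and hyper-methylated
targets; with signed d a hyper-methylated target's "similar" calls would
depend on its direction.

## 9. The synthetic generator

The generator plants the study conditions: 12 patients × 7 regions,
negative-binomial coverage (mean 30, dispersion 0.1 — keeping
P(coverage < 15×) small, as real cohorts are analysed after a 15× floor),
uniform per-cell missingness at 0.1, and four spatial kinds. Steep
patterns put the whole effect at the TE|P5 boundary; shallow patterns
interpolate it linearly across the seven ordinals (the simplest monotone
family, sufficient for Kendall recovery); flat is constant; fluctuating
draws region means independently. The default total effect is 0.3 with
per-patient sd 0.03 and per-cell beta sd 0.05 — chosen once so that both
planted classes are recoverable but not trivially separable from counting
noise. Sites sit in loci of three same-kind CpGs 25 bp apart (typical
island spacing, and the scale the ±30 bp neighbour analysis and 250 bp
region merging operate on), loci 10 kb apart round-robin across kinds.
Per-site RNG sub-streams derive from one global seed, so any site can be
regenerated in isolation and reruns are byte-identical.

The survival generator emulates a 59-patient validation cohort with ~18
events: each patient-site is low-difference with probability 0.3;
patients with ≥ 2 such sites carry `planted_hr = 4` times the baseline
exponential hazard; censoring is an independent exponential calibrated to
0.7. Low-difference sites are drawn within ±3.6 % relative difference and
high-difference sites between 8 % and 40 %, so the 5 % working threshold
recovers the planted status exactly. With ~18 events the Cox log-HR
standard error is ≈ 0.57 even under perfect classification, so individual
cohort estimates scatter around the planted value by more than a factor
of two in roughly a quarter of replicates — an event-count property the
recovery tests make visible, not an estimator defect.

What the generator does *not* emulate: read-level bisulfite artifacts,
strand asymmetry, SNP interference, spatially varying missingness,
covariate-dependent censoring, and any correlation between methylation
level and coverage. Passing tests therefore demonstrate the pipeline's
statistical behaviour under its own assumptions, not performance on real
tissue.

## 10. Numerical notes

- The detection-frequency EM (two Gaussian components on per-site
  detection counts) uses quantile initialisation, tolerance 1e-8, ≤ 500
  iterations, and asserts a non-decreasing log-likelihood each step; the
  kept-site threshold is the smallest count whose high-component posterior
  reaches 0.5. Degenerate count distributions fall back to a fixed
  threshold with a warning.
- Fisher–Jenks binning is an exact O(k·n²) dynamic programme on sorted
  values; the tests check it against exhaustive partition search.
- The fixed-width Moran's-I binning reproduces the 11-bin scheme: an open
  bin at ≤ −0.025, nine interior bins of width 0.025 on (−0.025, 0.2], and
  an open bin above 0.2.
- The ±30 bp neighbour window is closed (a neighbour at exactly 30 bp
  counts).
- CpGs are keyed by (chromosome, 1-based forward-strand position);
  symmetric-strand merging is not performed.

## Problem sizes

The shipped tests run the full discovery pipeline at 600 sites × 84
samples (100 sites per planted kind, seed 7), 10⁴-shuffle null
calibrations, 1000-chromosome merge-oracle sweeps, and 100–200-replicate
survival simulations — sizes chosen so the whole suite exercises every
stage end to end in under a minute on one core while keeping Monte-Carlo
noise well below the tolerances asserted.
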