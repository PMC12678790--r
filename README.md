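# methgrad

Spatial DNA-methylation gradient analysis across tumor-adjacent tissue.

## The problem

In resected lung adenocarcinoma, tissue can be sampled at seven ordered
positions along the tumor-to-normal axis: tumor core (TC), tumor edge (TE),
histologically normal tissue at 0–5, 5–10, 10–15 and 15–20 mm beyond the
visual tumor boundary (P5, P10, P15, P20), and paired-distal normal tissue
(PN). Per-CpG methylation from reduced-representation bisulfite sequencing
then shows two qualitatively different spatial behaviours:

- **steep** changes — the whole methylation difference sits at the TE|P5
  visual boundary (tumor-confined alteration), and
- **shallow** changes — a monotone gradient across all seven positions,
  i.e. tumor influence reaching past the visible boundary into
  histologically normal tissue.

`methgrad` implements the full analysis that separates, scores and
exploits these patterns, for cohorts laid out as patients × 7 regions:

1. **I/O and filtering** — Bismark-style coverage files; per-cell coverage
   floor (< 15× set missing); detection-frequency filter via a
   two-component Gaussian-mixture EM (or a fixed threshold such as 68 of
   84 samples).
2. **Significance matrices** — per CpG, paired one-tailed Wilcoxon
   signed-rank tests for all 21 region pairs build a symmetric 7×7 binary
   matrix `sig` with a direction matrix, plus 42-dimensional status
   vectors, cosine similarity between neighbouring sites (±30 bp), and
   binning utilities (fixed-width 0.025 scheme, quantile, GMM-EM,
   Fisher–Jenks natural breaks).
3. **Moran's I** — spatial regularity of each matrix under
   inverse-distance grid weights,

   I = Σᵢ Σⱼ≠ᵢ wᵢⱼ (xᵢ − x̄)(xⱼ − x̄) / (S² Σᵢ Σⱼ≠ᵢ wᵢⱼ),  S² = (1/n) Σᵢ (xᵢ − x̄)²,

   with one observation per matrix cell at integer (row, col) coordinates,
   wᵢⱼ = 1/dᵢⱼ, and a cell-shuffle null (mean −1/(n−1)).
4. **Trend classification** — the steep rule (significance only between
   {TC, TE} and {P5..PN}, at least three per tumor row, one direction),
   then Kendall's tau-b along the region order (tie-corrected normal P)
   with the shallow screens (P < 0.01, tumor–PN and within-normal
   significance, no contradicting pair).
5. **Regions and annotation** — merge same-trend changed sites (≥ 3 sites,
   gaps ≤ 250 bp) into steep/shallow/mixed rise/decline regions, median
   region methylation, mapping onto gene bodies and 2 kb strand-aware
   promoters from GTF, and feature-track overlap proportions (BED).
6. **Clustering** — row z-scoring, hand-rolled deterministic Ward.D2
   (validated against `hclust`), bootstrap clade support, Newick export.
7. **Prognosis** — per-site relative difference d = 100·(adjacent −
   tumor)/tumor between paired tumor/adjacent samples, low- vs
   high-difference classification over a 3–15 % threshold sweep,
   Kaplan–Meier / log-rank / Cox hazard ratios, the combined ≥ N-of-panel
   risk model, and TNM-stage cross-tabulation.
8. **Synthetic cohorts** — a seeded generator planting steep / shallow /
   flat / fluctuating spatial trends with beta-binomial counts,
   negative-binomial coverage and missingness, plus survival cohorts with
   a planted hazard ratio, so every stage is testable without restricted
   patient data.

## Worked example

```r
library(methgrad)

cfg <- cohort_config(sites_per_pattern = 20, seed = 7)   # 12 patients x 7 regions
sim <- simulate_methylation_cohort(cfg)
cohort <- cohort_from_simulation(sim)                    # 15x floor applied
cl <- classify_sites(cohort)
attr(cl, "summary")
#>      steep_rise   steep_decline    shallow_rise shallow_decline       unordered
#>               8              10              23              21              58

regions <- merge_changing_sites(cl)
table(regions$category)
#>   mixed_decline      mixed_rise shallow_decline    shallow_rise
#>               1               1               4               6
```

120 planted sites give 62 classified trend sites; the shallow-dominated
region table reflects that steep calls are rarer under the strict
boundary-only rule (see the methods vignette). The prognosis stage on a
simulated 59-patient cohort (planted hazard ratio 4 for patients with ≥ 2
low-difference sites):

```r
rec <- simulate_prognosis_cohort(prognosis_config(seed = 23))
cmb <- combined_model(rec, unique(rec$site), N = 2, threshold = 5)
#> combined model: HR = 4.29 (95% CI 1.18-15.60), log-rank P = 0.01608
```

The hazard ratio of the high-risk group (≥ 2 of 6 sites with |d| < 5 %)
recovers the planted value of 4; the log-rank P comes from the
chi-squared distribution with one degree of freedom.

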