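# bodymaps

Case-control analysis of bodily sensation maps (BSMs): the colouring-task
data in which participants mark, on a human silhouette, where in their body
they feel emotions, pain, or heightened tactile / nociceptive / hedonic
sensitivity. The package is written for pain researchers and
biostatisticians who want to compare such maps between a patient group and
matched controls — the setting where chronic-pain cohorts show subgroup-
specific pain topographies (arm-focused in CRPS, lower back in low back
pain, feet in neuropathic pain, diffuse in fibromyalgia) and a general
*dampening* of the bodily maps of emotions.

Because raw colouring data of this kind are rarely shareable, the package
ships a calibrated synthetic-cohort generator that reproduces the
statistical structure of such a study (group sizes, demographics, spatially
coherent colouring, dampened patient emotion maps), so the entire pipeline
is testable end to end without any external data.

## What it computes

* **Silhouette masks and an 8-region atlas** — a procedural body outline
  (one-panel for emotions; two mirror-identical front/back panels for pain
  and sensitivity) partitioned into head, shoulders, arms, hands, upper
  torso, lower torso, legs, feet. All statistics are mask-agnostic; a real
  silhouette PNG can be dropped in.
* **Preprocessing** — binary conversion (a pixel is coloured iff opacity
  > 0), activation/deactivation overlay into −1/0/1 signed emotion maps,
  outside-outline cleaning, empty-body semantics (controls' empty bodies
  are intentional zero maps; patients' unflagged empties are missing data),
  the 10% colouring quality-control rule, and affected-side mirroring.
* **Control matching** — eligibility screening (no chronic pain, NRS ≤ 3,
  BPI now/24h-mean < 5, optional strict mode) and greedy scarcest-first
  age- and gender-matching with low-pain tie-breaks; an exhaustive optimal
  assignment mode for small pools.
* **Mass-univariate maps** — at every in-mask pixel, a two-sample t test
  on the signed emotion values or a pooled two-proportion z test
  `z = (p̂_A − p̂_B) / sqrt(p̂(1−p̂)(1/n_A + 1/n_B))` on the binary maps,
  with Benjamini–Hochberg FDR thresholding over exactly the m in-mask
  pixels.
* **Scalar statistics** — whole-body and per-ROI coloured extents,
  Mann–Whitney U with exact enumeration (n ≤ 12) and signed effect size
  r = z/√N, Welch t, Holm–Bonferroni adjustment, Pearson correlation
  panels, and Fisher r-to-z contrasts of independent correlations
  `z = (atanh r₁ − atanh r₂) / sqrt(1/(n₁−3) + 1/(n₂−3))`.
* **Robust ANOVA** — a between×within (group × condition) ANOVA on
  trimmed means with winsorized covariance estimates and Johansen-type
  approximate F statistics, for the emotion-extent, sensitivity and
  self-rating analyses.

## Worked example

```r
library(bodymaps)

# the Fisher r-to-z contrast of two correlations (r = 0.74 vs 0.40, n = 118 each)
fisher_z_compare(0.74, 118, 0.40, 118)
#> Fisher z = 3.995 (r1 = 0.740, n1 = 118 vs r2 = 0.400, n2 = 118), p = 6.472e-05

# a small end-to-end study: simulate, QC, match, map comparisons, tests
cfg <- pipeline_config(
  sim = sim_config(n_patients = 24, n_control_pool = 96,
                   subgroup_counts = c(CRPS = 8, NP = 5, FM = 3,
                                       LBP = 6, other = 2),
                   seed = 7),
  seed = 7)
res <- run_pipeline(cfg)
res
#> bsm_report (seed 7): 24 matched pairs; 12 map contrasts

res$report$extent_tests[1:2, c("name", "effect_r", "median_patients",
                               "median_controls", "p_adjusted")]
#>                              name  effect_r median_patients median_controls   p_adjusted
#> pain_current  extent_pain_current 0.8016271      0.09479983      0.00000000 1.397345e-07
#> pain_chronic  extent_pain_chronic 0.8012830      0.14242721      0.01917693 1.577792e-07

res$report$emotion_anova
#>        effect statistic df1      df2            p
#> 1       group  3.328885   1 26.82010 7.923288e-02
#> 2   condition 33.198040   6 19.89703 2.378192e-09
#> 3 interaction  1.245437   6 19.89703 3.258881e-01
```

The extent tests say that simulated patients colour far larger body areas
for current and chronic pain than their matched controls (medians 0.09 and
0.14 of the body versus 0 and 0.02, rank-biserial-style r ≈ 0.8); at this
small n the emotion-dampening group effect is visible but not yet
significant — at the default study scale (118 per group) it is (see
below). `run_pipeline(cfg, out_dir = "out")` additionally writes `qc.csv`,
`matches.csv`, `tests.csv`, `report.json` and rendered PNG maps (group
frequency panels plus the FDR-thresholded difference map).

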