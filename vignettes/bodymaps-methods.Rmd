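---
title: "Methods: case-control analysis of bodily sensation maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control analysis of bodily sensation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodymaps)
```

## The problem

In a bodily-sensation-map (BSM) study, participants colour human
silhouettes to indicate where in the body they feel specific emotions
(with separate silhouettes for increased and decreased activation), where
they currently or chronically feel pain, and which body areas they
experience as particularly sensitive to pain, to light touch, or to
pleasant touch. A case-control design compares a chronic-pain patient
group against controls matched on age and gender, asking two kinds of
questions: *where* do the groups differ (pixel-level topography), and *how
much* of the body is involved (scalar extents, by region or whole-body)?

This vignette documents the statistical procedures, their assumptions, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices open.

## Data representation and preprocessing

Every map lives on a `silhouette_mask`: emotion tasks on a one-panel mask
(no front/back distinction, since visceral emotion sensations do not
localise to the body surface), pain and sensitivity tasks on a two-panel
mask (front panel on the left of the drawing, back panel on the right).
The two panels are mirror-identical, and each panel is left-right
symmetric at pixel level, which makes affected-side mirroring an exact
involution. An atlas partitions the in-mask pixels into eight anatomical
regions (head, shoulders, arms, hands, upper torso, lower torso, legs,
feet).

Preprocessing decisions:

* **Binarization.** A pixel counts as coloured iff its opacity is strictly
  positive. Opacity accumulates with repeated strokes and differs across
  input devices, so it carries no comparable information; the threshold is
  configurable but 0 is the default and the analysed quantity is always
  the binary map.
* **Signed emotion maps.** Activation minus deactivation per pixel, coded
  +1/0/−1. A pixel coloured on *both* silhouettes is coded 0: the three-
  level coding forces a conflict rule, and the symmetric difference is the
  assumption-free choice.
* **Empty bodies.** Patients could flag an intentionally empty body;
  controls could not. An empty control body is therefore treated as an
  intentional zero map, while an empty, unflagged patient body is missing
  data: dropped from that task's analyses only, with the participant
  retained elsewhere (listwise within task, not across tasks).
* **Outline screening.** Colouring outside the body outline is removed and
  quantified as `outside_fraction` (coloured-outside / coloured-total, 0
  for an empty map). Responses above a 0.5 fraction are flagged for review
  but never auto-excluded — the screen is informational, mirroring a
  visual check that excludes nobody.
* **The 10% rule.** A participant is retained iff in at least one task
  they coloured ≥ 10% of that task's own mask (the two-panel tasks use the
  two-panel pixel count as denominator; whether a fixed denominator should
  be shared across tasks is not determinable from the methodology, and the
  per-task mask is the internally consistent reading). The boundary is
  inclusive. QC runs before matching, so matched controls are always
  QC-clean.
* **Affected-side mirroring.** For lateralised conditions the two-panel
  maps can be flipped so the affected side is always drawn on the right
  ("right of the drawing" = higher column index — one convention, used
  everywhere). Each panel flips about its own vertical midline; the
  operation preserves coloured counts and is its own inverse.

## Control matching

Eligibility: no self-reported chronic pain condition, current pain
NRS ≤ 3, and BPI *now* and *24-hour mean* below 5. The NRS cut-off is
stated as "less than 3" in some descriptions of this design yet matched
cohorts contain controls with NRS exactly 3; the package therefore
defaults to the inclusive reading (≤ 3) and offers the exclusive one via
`eligibility_criteria(nrs_inclusive = FALSE)`. A `strict_mode` restricts
both BPI items to {0, 1, 2}.

Matching is greedy without replacement. Processing order is
scarcest-first: patients with the fewest same-gender eligible candidates
are matched first, which protects the rare stratum (men, in a cohort that
is 87% women) from being exhausted by flexible patients. Within a patient,
candidates are ranked by |age difference|, with exact ties broken by lower
current pain (NRS), then lower BPI 24-hour mean, then a seeded uniform
draw — "prioritising low pain" acts only within exact age ties, because an
age tolerance traded against pain would need a trade-off constant the
design does not supply. `method = "optimal"` computes the exhaustive
minimal-total-age-difference assignment (small pools; used as a quality
bound on the greedy solution in the test suite).

## Pixel-level statistics

At every in-mask pixel independently, group A (patients) is compared with
group B (controls):

* signed emotion maps: a two-sample t test on the −1/0/1 values. Welch's
  unequal-variance form is the default (the safer choice when group
  variances differ); `var_equal = TRUE` gives the pooled-variance t.
* binary pain/sensitivity maps: the pooled two-proportion z test,
  $z = (\hat p_A - \hat p_B)\big/\sqrt{\hat p(1-\hat p)(1/n_A + 1/n_B)}$.

Statistics are signed (positive = larger in patients) so "higher in
patients" and "higher in controls" pixels remain distinguishable in the
rendered maps. P values are two-sided. Pixels that are constant in both
groups (e.g. never coloured by anybody) get statistic 0 and p = 1, and —
deliberately — stay inside the multiplicity family: correction is "for
the number of pixels within the silhouette", i.e. Benjamini–Hochberg
step-up over exactly the `m = n_in_mask` pixels of that task's mask, with
the one-panel and two-panel masks contributing their own separate m. The
`q` grid is the BH-adjusted p; `significant` is `q ≤ α` with α = 0.05 by
default. No spatial smoothing or cluster inference is applied anywhere —
inference is purely pixel-wise, and the spatial coherence of colouring
enters only through the dependence structure BH is known to tolerate.

## Scalar statistics

**Extents.** The coloured extent of a map is the coloured in-mask fraction
(both panels jointly for two-panel tasks); per-ROI extents divide by the
region's own size. For signed maps "coloured" means nonzero, with
activation-only and deactivation-only variants available.

**Mann–Whitney U.** Group extent comparisons are rank-based. For pooled
sizes ≤ 12 the two-sided p is exact, by enumeration of all
$\binom{N}{n_x}$ group assignments on the observed (tied) ranks; above
that, the normal approximation with tie and continuity corrections is
used — the two regimes agree to better than 0.01 at 10+10 already. The
effect size is the signed $r = z/\sqrt N$, positive when the first sample
tends larger. Families of extent tests are Holm–Bonferroni adjusted
(familywise control for small scalar families; FDR is reserved for the
pixel maps).

**Robust between×within ANOVA on trimmed means.** For group × condition
designs (7 emotions; 3 sensitivities; 9 self-rating items) with skewed,
zero-inflated extents, cell means are replaced by γ-trimmed means
(γ = 0.2 per tail by default, the conventional robust-ANOVA default), and
the covariance of each group's trimmed-mean vector is estimated as
$(n-1)S_w / (h(h-1))$ with $S_w$ the winsorized covariance matrix and
$h = n - 2\lfloor\gamma n\rfloor$ the effective sample size. Each effect
(group, condition, interaction) is tested with Johansen's approximate F:
$T = (C\hat\mu)'(C V C')^{-1} C\hat\mu$, scaled by
$c = q + 2A - 6A/(q+2)$ against $F(q,\; q(q+2)/(3A))$, where $A$
aggregates the per-group trace terms. With γ = 0 the procedure reduces
exactly to the untrimmed Johansen test, which is how it is validated (an
independently coded oracle in the test suite, agreement to 1e−6; null
rejection rate within [0.03, 0.07] at nominal 0.05 over 1000
simulations). Degrees of freedom are always reported as the pair
(df1, df2). Constant data in all cells returns statistic 0 and p = 1
rather than an error; singular winsorized covariances fall back to a
pseudo-inverse.

**Correlation contrasts.** Correlation panels are Pearson (the r-to-z
machinery presumes them), computed on pairwise-complete observations, with
per-group Holm adjustment. Two independent correlations are compared with
Fisher's r-to-z:
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$.
The seven BPI interference items are condensed to their arithmetic mean
(up to 3 missing items tolerated).

## The synthetic cohort generator

`sim_config()` defines the study conditions the package is built around:
118 patients (42 CRPS, 24 neuropathic, 12 fibromyalgia, 32 low back pain,
8 other), a control pool three times that size, 87% women, ages truncated
normal with mean 44 and SD 12 on [18, 80]. Patients carry elevated NRS/BPI
scores and higher negative (but lower happiness) momentary self-ratings,
with patients' happiness additionally depressed by their BPI mean
interference; the control pool deliberately mixes eligible members with
ineligible ones (chronic pain flags, NRS/BPI above the cut-offs) so
matching has real screening to do.

Colouring is a **blob model**: each map is a clipped sum of k disk blobs
(k Poisson, radii uniform, opacities uniform), *not* pixel-iid noise —
real colouring is spatially autocorrelated, and FDR behaviour under that
dependence is the realistic thing to test. Patients' pain and nociceptive
blobs are drawn from their subgroup's placement prior (arms on the
affected side for CRPS, the lower-back panel region for LBP, feet for NP,
diffuse for FM) with probability 0.6 (0.5 for sensitivity), the remainder
diffuse. Per-participant log-normal factors (severity, SD 0.5 on the log
scale, shared across pain/nociceptive tasks; expressiveness, SD 0.25,
shared across emotion tasks) couple a participant's extents across tasks
— this is what makes the current-vs-chronic extent correlation strong in
patients, and it sets the between-subject variance against which the
emotion dampening must be recovered. The expressiveness SD was chosen so
that the generator's own parameter-recovery contract holds: a multiplier
of 0.75 must be detectable by the trimmed ANOVA with power ≥ 0.9 at
118 per group.

`emotion_extent_multiplier_patients` (default 0.75) scales patients'
emotion blob *areas*, implementing the dampening of patients' emotion maps
at roughly the ratio observed in chronic-pain cohorts (patient ≈ 0.77 of
control extent). `null_mode = TRUE` draws patients' maps from the control
distributions with multiplier 1 — the group map distributions are then
identical by construction, which is the basis for the false-positive
calibration tests.

Blob rates and radii were calibrated once, before any acceptance run,
against the qualitative anchors of published chronic-pain BSM cohorts —
patients' chronic-pain extent median near 0.14 versus ≈ 0.03 for controls,
current-pain medians near 0.10 versus 0, nociceptive-sensitivity means
near 0.13 versus 0.06, comparable tactile/hedonic extents, emotion extents
around 0.15–0.19 with neutral far smaller. These are tuning goals, not
asserted constants: the realized medians (slightly below the anchors,
because overlapping blobs and mask-edge clipping compress extents) are
whatever the generator produces and are reported, never assumed, by the
tests and the acceptance script.

Reproducibility: every response stream is seeded by a hash of
(seed, participant id, task), so cohorts are bit-reproducible, invariant
to generation order, and any single map can be redrawn in isolation.
Radii are specified at a reference mask height of 256 and scaled to the
actual mask, so extents are resolution-invariant.

**Default problem sizes.** The default masks are 176×88 (one-panel,
≈ 7,150 in-mask pixels) and 176×176 (two-panel, ≈ 14,300) — a resolution
at which a desk-scale simulation study (hundreds of full cohorts) stays
interactive while pixel counts remain far above anything the step-up
correction is sensitive to; the statistics are resolution-agnostic by
construction. The default control pool of 354 (3:1) keeps full-cohort
memory modest while leaving matching a genuine surplus of candidates;
`n_control_pool` scales it up when the pool itself is under study.

**What the generator does not emulate.** Device/pressure opacity dynamics
(irrelevant after binarization); per-emotion topographic archetypes
(emotion blobs are spatially uniform — group *extent* structure is
modelled, pixel-level emotion topography is not); education or other
covariates; every printed cross-correlation of a real cohort (e.g. the
fear-by-current-pain correlation difference is not built in). Passing
tests therefore validate the statistical machinery under realistic
spatial dependence and cohort structure — they do not certify pixel-level
realism of emotion topographies.

## The pipeline

`run_pipeline()` chains the stages in study order — simulate (or load),
clean and resolve empties, QC, match, pixel-wise comparisons for the two
pain and three sensitivity maps (proportion z) and seven emotions
(signed t), whole-body Mann–Whitney extent tests (Holm family), robust
group×emotion, group×sensitivity and group×self-rating ANOVAs, the
correlation panel with Fisher contrasts, and the BPI interference
correlations — and optionally writes `qc.csv`, `matches.csv`, `tests.csv`,
`report.json`, and per-contrast PNG renderings (group frequency panels;
difference panel showing only FDR-significant pixels, red = higher in
patients, blue = higher in controls). Identical config + seed produces a
byte-identical `report.json`.

The package is driven from R; the pipeline functions and this vignette are
its interface, and `scripts/acceptance.R` is a worked, runnable record of
the full-scale analysis.

## Known limitations

* The Johansen approximation can be liberal for very small groups with
  heavy trimming; the implementation enforces only h ≥ 2 and leaves
  design-power questions to the user.
* Greedy matching is order-dependent by construction; the optimal mode is
  exhaustive and limited to small strata (≤ 10 patients, ≤ 16 controls
  per gender).
* Exact Mann–Whitney enumeration stops at pooled n = 12; beyond that the
  corrected normal approximation is used.
* The procedural silhouette is schematic; anatomical realism of region
  shapes matters only for visualisation, not for any statistic.
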