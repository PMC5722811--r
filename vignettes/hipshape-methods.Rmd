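---
title: "Hip shape modelling and osteoarthritis association: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hip shape modelling and osteoarthritis association: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipshape)
```

This vignette records how the pipeline is defined, which choices were
genuinely open and how they were settled, and what the synthetic cohort
does and does not establish about real data.

## Shape model

### Coordinate conventions

A configuration is an ordered set of P = 58 points in the image pixel
frame: origin top-left, y increasing downward, as landmark tools export
points from DXA rasters. Internally a configuration is a stacked vector
`c(x_1..x_P, y_1..y_P)`; a cohort is an n × 2P matrix. Template point
indices are anatomical labels: point i refers to the same anatomical locus
on every hip. Left hips are mirrored about a vertical axis into the
right-hip frame *before* any alignment (`mirror_to_right()`); under the
label convention no re-indexing is needed, and the aligner itself never
reflects (the similarity group is scale–rotation–translation only, so
anatomical chirality is preserved).

### Procrustes superimposition

`align_pair()` solves 2D ordinary Procrustes in closed form in the complex
plane: with centred configurations as complex vectors z (shape) and w
(reference), the optimal scale-rotation is a = (z*ᵀw)/(z*ᵀz), which cannot
contain a reflection. `gpa()` iterates: align all shapes to the current
mean, recompute the mean, re-centre and rescale it to unit centroid size,
until the RMS change of the mean is below `tol = 1e-8` or `max_iter = 100`
(in practice convergence takes fewer than 10 iterations on all cohorts
exercised in the tests). The initial reference is the first shape, centred
and scaled to unit size; a permutation-invariance test guards against
order sensitivity. Full Procrustes (with scaling) is used, so size is not
a model variable. No tangent-space projection is applied before PCA: PCA
is performed directly on aligned coordinates, the standard
point-distribution-model recipe. At the Procrustes variances seen here
(per-coordinate residuals well under 1% of centroid size) the curvature of
shape space is negligible relative to sampling error.

One property worth stating explicitly because it shaped both the tests and
the truth-recovery helpers: a GPA solution is only defined up to one
global similarity transform. The orientation of the fitted frame follows
the initial reference, i.e. the arbitrary orientation of the first input
shape. Mode *scores* and eigenvalues are invariant to this; eigenvector
*coordinates* are not. Any comparison between fitted eigenvectors and
externally defined deformation fields must first rotate the fields into
the fitted frame (`fields_in_model_frame()` uses the optimal rotation
carrying the template onto the fitted mean). Comparing in mismatched
frames silently inflates principal angles by the global rotation.

### PCA, scores, reconstruction

`fit_shape_model()` eigen-decomposes the covariance (not correlation)
matrix of aligned coordinates. Similarity alignment removes 4 degrees of
freedom in 2D, so at most min(n − 1, 2P − 4) modes are meaningful; `k`
defaults to 10 retained modes for the association battery, and variance
fractions are always taken against the full covariance trace. Eigenvector
sign is arbitrary in PCA, and association signs flip with it; for
reproducibility each eigenvector is oriented so its largest-absolute
loading is positive (ties broken by lowest index). Raw projections are
standardised by the training cohort's mean and SD, so training scores have
mean 0 and SD 1 per mode by construction; `reconstruct()` de-standardises
and adds back along the eigenbasis, and with all modes retained the round
trip reproduces an aligned shape to numerical precision. Scores beyond
±4 SD are *flagged* for review (`flag_outliers()`), not auto-excluded,
mirroring the manual-check workflow used when such scores usually indicate
point-placement error.

### Operator placement quality control

`point_to_point_accuracy()` scores an operator by the median Euclidean
distance, pooled over all (image, point) pairs, between the operator's
point and the average over *all* operators — including the scored one;
excluding self would change the value, so the inclusion is deliberate and
tested. The pooled median (not a median of per-image medians) is the
literal reading of a "median point-to-point difference". A median ≤ 3
pixels denotes acceptable accuracy.

## Outcome construction

The Croft aggregation of component grades is implemented as: 0 none;
1 osteophytosis only; 2 joint space narrowing (JSN) only; 3 two of
{osteophytosis, JSN, sclerosis, cysts}; 4 three of those four; 5 the
grade-4 criteria plus femoral head deformity. Feature presence means any
relevant site or region at grade ≥ 1 (the mild cut-off used for primary
analyses). The mapping is monotone in every component grade, and the
moderate (≥ 2) and severe (≥ 3) RHOA definitions are nested. One corner
case is worth flagging: a reading with sclerosis *and* cysts but no
osteophyte or JSN grades 3 under this scheme, although descriptions of
moderate RHOA usually say it "requires osteophytes or JSN". The scheme is
implemented as cited; the synthetic generator never produces that corner
(every generated case carries osteophytes or JSN by construction), so the
discrepancy cannot contaminate generated cohorts. Printed prevalences use
half-up rounding to one decimal (`round_half_up()`), matching how
prevalence tables are conventionally formatted; base `round()` rounds half
to even and can differ in the last digit.

## Association models

Binary outcomes use maximum-likelihood logistic regression; WOMAC uses the
proportional-odds model. Choices that were open:

* **CI method.** Wald intervals on the log-odds scale,
  exp(β̂ ± 1.96·SE), with two-sided Wald p-values. Profile-likelihood
  intervals differ negligibly at these sample sizes and prevalences.
* **Ordinal categories.** WOMAC's 0–20 tail is sparse; levels are
  collapsed upward until every modelled category holds ≥ 5 observations
  (configurable). A two-level outcome is fitted by the binary logistic
  likelihood, to which the proportional-odds model reduces exactly when
  only one threshold remains.
* **Race coding.** Indicator contrasts with "white" (the largest
  category) as reference. A single-level race column is dropped rather
  than sent to the contrast builder.
* **Missingness.** Complete-case per outcome; each result row reports its
  own `n_used`.
* **Proportional odds.** Asserted, not tested, matching how the model is
  typically applied in this setting.
* **Separation.** Diagnosed (non-convergence or |β̂| > 10) and raised as
  an error naming the exposure; in the battery such cells are recorded in
  an `error` column rather than aborting the run.

The battery (`run_association_battery()`) fits one model per
(mode, outcome, adjustment) cell over the default outcome surface — RHOA
at Croft ≥ 2 and ≥ 3, each osteophyte site at grades ≥ 1 and ≥ 2, each JSN
region and sclerosis at grade ≥ 1, both binary pains, and ordinal WOMAC —
and flags significance at the Bonferroni threshold 0.05/m for the m modes
tested (0.005 for the default ten).

## Synthetic cohort generator

The generator emulates an elderly male cohort with a readable right-hip
radiograph: n = 4100 by default; age 72.8 (5.7) years, height 174.4 (6.8)
cm, weight 83.6 (12.9) kg; race 90.7% white, 3.3% Asian, 3.2% African
American, 2.8% other.

### Template and deformation fields

`make_hip_template()` draws a stylised right-hip outline on a 600-pixel
canvas from circular arcs and quadratic Béziers: a superior acetabular arc
(one medial "eyebrow" key point, two lateral key points on the outer rim),
the femoral head arc, the superior head–neck junction running to the
greater trochanter, lateral and medial shaft edges, a lesser-trochanter
bump, and the inferior neck (calcar). Segment point counts are allocated
by largest remainder for non-default P (minimum 20). The geometry is an
idealisation labelled by construction — it is not calibrated to clinical
alpha or centre-edge angles.

`make_deformation_fields()` plants four labelled fields: *pincer-like*
(lateral acetabular rim displaced laterally and inferiorly, extending
coverage of the head — verified geometrically by the increase in the
coverage arc subtended at the head centre), *cam-like* (radial outward
displacement at the superior head–neck junction, zero elsewhere in raw
form), lesser-trochanter prominence and a neck-shaft-angle rotation as
nuisance fields. Raw fields are projected off the similarity tangent space
at the template (translations, rotation, scaling) so that planted
variation cannot be absorbed by Procrustes alignment, then Gram–Schmidt
orthonormalised in the order above. Default loading SDs are 6, 4, 3, 2
pixels — well-separated eigenvalues so fitted modes are identifiable — with
1 pixel of isotropic landmark noise (the order of trained-operator
placement error) and random similarity jitter (scale 0.9–1.1, rotation
±10°, translation ±20 px) that GPA must remove.

### Outcomes with known truth

Outcomes are planted on the *true* loadings (standardised by their own
cohort SD), not on fitted scores, so the ground truth is model-free and
fitted-mode/true-field agreement is itself something the tests verify.
Case status follows logistic models with per-field log odds ratios
(defaults: RHOA — pincer log 1.23, cam log 1.37; exam pain — cam log 1.19;
walking pain — cam log 1.14; WOMAC — cam log 1.15) plus small centred
covariate effects. Intercepts are not fixed numbers: each is calibrated by
root-finding so the cohort's mean predicted probability equals its target
(RHOA 7.1%, exam pain 11.4%, walking pain 20.2%), which holds the
prevalence at any n and makes the "all effects zero" case land on target
by construction.

RHOA cases receive component grades that guarantee Croft ≥ 2: JSN-only
patterns (grade 2) or two/three-feature patterns always including
osteophytes or JSN (grades 3–5), with the three-plus patterns set to 34%
of cases so the severe (Croft ≥ 3) share lands near its 2.4% target.
Non-cases are grade-0 dominant with an osteophyte-only stratum (22% of
non-cases, Croft grade 1) sized so the lateral acetabular osteophyte
marginal — the most common single feature, by design — lands near 19.2%.
WOMAC is drawn from a proportional-odds model whose baseline is a
right-skewed negative-binomial shape over 0–20 with mean ≈ 0.9. All
randomness flows from one seed with fixed per-stage offsets, so stages
are independently reproducible.

### What the generator does not emulate

Landmark noise is isotropic and independent across points; real placement
error is correlated along contours and anisotropic (larger along the bone
edge than across it). Deformity fields are single fixed directions, not
the curved, multi-scale variation of real anatomy; covariates are
independent of shape, so confounding is absent unless planted; radiograph
grades are generated from case status rather than from shape itself, so
"cases look like cases" only through the planted model. Passing tests
therefore establish the *software* recovers what was planted under the
stated conditions — not that ten modes explain any particular variance
share in real cohorts, nor that real effect sizes equal the planted ones.

## Numerical choices and test conditions

* GPA: `tol = 1e-8` (RMS mean change), `max_iter = 100`; objective
  recorded per iteration in a gauge where the mean has unit centroid size,
  so the renormalisation step cannot inflate it.
* Eigen sign convention and score normalisation as above; degenerate
  cohorts (n ≤ 2P) are permitted with rank capped at min(n − 1, 2P − 4)
  and a warning.
* The pipeline YAML key for cohort size is `n_shapes`, not `n`: YAML 1.1
  resolves a bare `n` key to a boolean.
* Test problem sizes, chosen to make Monte-Carlo error small relative to
  the asserted tolerances while keeping the default suite around a minute:
  subspace recovery at n = 1000 with landmark noise 0.4 px (20% of the
  smallest planted loading SD; principal angles < 5°, mode SDs within
  10%); logistic effect recovery with 200 replicates at n = 4000; ordinal
  recovery with 30 replicates at n = 4000; null calibration with 200–500
  replicates; prevalence calibration at n = 10,000; the deterministic
  demo pipeline at n = 500.

## Known limitations

2D similarity shape only (no 3D, no size-and-shape or allometry);
no weighted or robust Procrustes; no missing-landmark handling;
proportional odds assumed rather than tested; the Croft corner case noted
above; and the template is a drawn idealisation, so mode shapes are
anatomically suggestive rather than clinically calibrated.
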