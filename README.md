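# hipshape

Statistical shape modelling of the proximal femur and acetabulum from
2D landmark configurations (as placed on hip DXA projections), and
epidemiological association of the resulting shape modes with radiographic
hip osteoarthritis (RHOA) and hip pain.

The package is for biostatisticians and musculoskeletal epidemiologists who
want a tested, reproducible implementation of the classic
Procrustes-plus-PCA pipeline for hip shape, together with the outcome
construction and regression battery used in cohort studies of hip OA —
plus a synthetic cohort generator with *known* planted deformities and
effect sizes, so every stage can be validated without access to
participant-level data.

## The model

Each hip is an ordered configuration of P = 58 landmarks
(x<sub>1</sub>, y<sub>1</sub>, …, x<sub>P</sub>, y<sub>P</sub>) in the image
pixel frame. The pipeline is the standard point-distribution model:

1. **Generalized Procrustes analysis (GPA).** Translation, rotation and
   scale are removed by full Procrustes superimposition (no reflections —
   left hips are mirrored into the right-hip frame beforehand). Shapes are
   iteratively aligned to the running mean; the mean is re-centred and
   rescaled to unit centroid size until its RMS change falls below 1e-8.
2. **PCA.** The covariance matrix of the aligned coordinate vectors is
   eigen-decomposed. Mode j is the eigenvector **v**<sub>j</sub>; a shape
   decomposes as **x** ≈ **x̄** + Σ<sub>j</sub> b<sub>j</sub>**v**<sub>j</sub>.
3. **Scores in SD units.** Raw projections b<sub>j</sub> are standardised by
   their cohort mean and SD, so each individual carries a vector of hip
   shape mode (HSM) scores in cohort-SD units; scores beyond ±4 SD are
   flagged for point-placement review.
4. **Outcomes.** Radiographic component grades (osteophytes 0–3 at four
   sites, joint space narrowing 0–4 at three regions, sclerosis, cysts,
   femoral head deformity 0–3) aggregate into the Croft grade 0–5; RHOA is
   Croft ≥ 2 (moderate) or ≥ 3 (severe). Pain outcomes: pain on internal
   rotation (binary), walking pain (0–4, dichotomised at ≥ 1), and the
   WOMAC 0–20 composite.
5. **Association.** For each mode and outcome, logistic (binary) or
   proportional-odds (WOMAC) regression gives an **odds ratio per SD** of
   the mode score, with Wald 95% CIs, unadjusted and adjusted for age,
   height, weight and race; ten modes are tested against a
   Bonferroni-corrected threshold of 0.05 / 10 = 0.005.

The synthetic generator plants labelled orthonormal deformation fields on a
drawn 58-point right-hip template — pincer-like acetabular over-coverage,
cam-like head–neck asphericity, and two nuisance fields — and generates
outcomes from logistic / proportional-odds models with stated log-odds
ratios and intercepts calibrated to target prevalences (RHOA 7.1%, exam
pain 11.4%, walking pain 20.2%).

## Worked example

```r
library(hipshape)

cohort  <- generate_cohort(default_sim_config(n = 4100, seed = 42))
aligned <- gpa(cohort$landmarks)
model   <- fit_shape_model(aligned, k = 10)
model
#> <shape_model> P = 58, k = 10 modes, n_train = 4100
#>   variance explained by retained modes: 43.2%

scores <- score_shapes(model, aligned)
scores[1:3, 1:5]
#>   image_id mode1 mode2 mode3 mode4
#> 1 img_0001 -0.06  0.30 -0.06  0.92
#> 2 img_0002 -1.47 -1.33 -0.19  2.53
#> 3 img_0003 -0.38 -0.40  0.69  0.17

outcomes <- build_outcome_table(cohort$readings, cohort$pain)
sprintf("RHOA prevalence: %.1f%%", 100 * mean(outcomes$rhoa_croft2))
#> "RHOA prevalence: 7.7%"

fit_logistic(outcomes$rhoa_croft2, scores$mode1,
             covariates = cohort$covariates,
             exposure_name = "mode1", outcome_name = "rhoa_croft2")
#>   exposure     outcome    model or_per_sd ci_low ci_high       p n_used adjusted
#> 1    mode1 rhoa_croft2 logistic     1.268   1.13   1.423 5.4e-05   4100     TRUE
```

Mode 1 of this synthetic cohort is the fitted counterpart of the planted
pincer-like field (planted OR 1.23 per SD on RHOA): the adjusted model
recovers OR 1.27 [1.13, 1.42], significant at the 0.005 threshold. Scores
are in cohort SD units, so the OR is the multiplicative change in odds of
RHOA per SD of that shape mode. `run_pipeline()` wraps all of the above
(plus operator placement QC, outlier flagging, ±2 SD mode-shape SVGs, and
the full mode × outcome battery) into one reproducible report bundle.

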