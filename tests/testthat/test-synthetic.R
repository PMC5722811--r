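test_that("the default template has 58 points with all anatomical key roles", {
  tpl <- make_hip_template()
  expect_equal(tpl$P, 58L)
  expect_equal(nrow(tpl$points), 58L)
  expect_setequal(names(tpl$key_points),
                  c("medial_acetabular", "lateral_acetabular_1",
                    "lateral_acetabular_2", "femoral_head", "femoral_neck",
                    "greater_trochanter", "lesser_trochanter"))
  expect_equal(tpl$roles[tpl$key_points], rep("key", 7), ignore_attr = TRUE)
  # segments partition 1..P
  expect_equal(sort(unlist(tpl$segments)), 1:58, ignore_attr = TRUE)
  # right-sided: lateral acetabular points at greater x than the medial one
  expect_gt(tpl$points[tpl$key_points[["lateral_acetabular_1"]], "x"],
            tpl$points[tpl$key_points[["medial_acetabular"]], "x"])
  expect_gt(tpl$points[tpl$key_points[["lateral_acetabular_2"]], "x"],
            tpl$points[tpl$key_points[["medial_acetabular"]], "x"])
  # deterministic
  expect_identical(make_hip_template(), tpl)
  expect_error(make_hip_template(10), "too small")
})

test_that("non-default point counts preserve structure", {
  for (P in c(20, 40, 80)) {
    tpl <- make_hip_template(P)
    expect_equal(tpl$P, P)
    expect_equal(sort(unlist(tpl$segments)), 1:P, ignore_attr = TRUE)
    expect_equal(length(tpl$key_points), 7L)
  }
})

test_that("template JSON serialization round trips", {
  tpl <- make_hip_template()
  path <- withr::local_tempfile(fileext = ".json")
  write_template(tpl, path)
  tpl2 <- read_template(path)
  expect_equal(tpl2$points, tpl$points, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tpl2$key_points, tpl$key_points)
  expect_equal(tpl2$segments, tpl$segments, ignore_attr = TRUE)
})

test_that("deformation fields are orthonormal with the stated support", {
  tpl <- make_hip_template()
  f <- make_deformation_fields(tpl)
  G <- f$fields %*% t(f$fields)
  expect_equal(G, diag(4), tolerance = 1e-10, ignore_attr = TRUE)
  # raw cam field is zero outside the head-neck junction indices
  cam_raw <- f$raw["cam_like", ]
  idx <- f$support$cam_like
  nonzero <- which(abs(cam_raw) > 0)
  expect_true(all(nonzero %in% c(idx, idx + tpl$P)))
  # raw pincer support sits on the acetabular segment
  expect_true(all(f$support$pincer_like %in% tpl$segments$acetabulum))
})

test_that("positive pincer loading extends acetabular coverage", {
  tpl <- make_hip_template()
  f <- make_deformation_fields(tpl)
  tv <- xy_to_shape(tpl$points)
  arc0 <- coverage_arc(tv, tpl)
  # +2 raw-SD of pincer deformation (default loading SD 6 px)
  arc2 <- coverage_arc(tv + 12 * f$fields["pincer_like", ], tpl)
  expect_gt(arc2, arc0 + 1)
})

test_that("sampled shapes honour the generative model", {
  cfg0 <- default_sim_config(n = 20, seed = 4, landmark_noise_sd = 0,
                             mode_sds = c(pincer_like = 0, cam_like = 0,
                                          nuisance_ltroch = 0, nuisance_nsa = 0))
  sh0 <- sample_shapes(cfg0)
  tv <- xy_to_shape(sh0$template$points)
  # zero loading + zero noise: every shape is a similarity image of the template
  for (i in 1:5)
    expect_lt(procrustes_distance(sh0$landmarks$coords[i, ], tv), 1e-10)

  cfg <- default_sim_config(n = 2000, seed = 4)
  sh <- sample_shapes(cfg)
  sds <- apply(sh$true_scores, 2, sd)
  expect_lt(max(abs(sds - cfg$mode_sds) / cfg$mode_sds), 0.05)

  # determinism: same seed bit-identical, different seed different
  sh_again <- sample_shapes(default_sim_config(n = 2000, seed = 4))
  expect_identical(sh_again$landmarks$coords, sh$landmarks$coords)
  sh_other <- sample_shapes(default_sim_config(n = 2000, seed = 5))
  expect_false(identical(sh_other$landmarks$coords, sh$landmarks$coords))
})

test_that("planted outcome models are calibrated to their prevalence targets", {
  cfg <- default_sim_config(n = 10000, seed = 6)
  cohort <- generate_cohort(cfg)
  outcomes <- build_outcome_table(cohort$readings, cohort$pain)
  # binomial Monte-Carlo error at n = 10,000
  tol3 <- function(p) 3 * sqrt(p * (1 - p) / cfg$n)
  expect_lt(abs(mean(outcomes$rhoa_croft2) - 0.071), tol3(0.071))
  expect_lt(abs(mean(outcomes$pain_internal_rotation) - 0.114), tol3(0.114))
  expect_lt(abs(mean(outcomes$walking_pain) - 0.202), tol3(0.202))
  # WOMAC is right-skewed with mean near 0.9
  expect_gt(mean(outcomes$womac), 0.7)
  expect_lt(mean(outcomes$womac), 1.1)
  expect_gt(mean(outcomes$womac == 0), 0.5)
  # every RHOA case carries at least one osteophyte or JSN feature
  cases <- rhoa_case(cohort$readings)
  has_oj <- binary_feature(cohort$readings, "any_osteophyte", 1) |
    binary_feature(cohort$readings, "any_jsn", 1)
  expect_true(all(!cases | has_oj))
  # lateral acetabular osteophytes are the most common single feature
  prev <- sapply(c("osteo_lat_acetabular", "osteo_lat_femoral",
                   "osteo_inf_acetabular", "osteo_inf_femoral", "jsn_medial",
                   "jsn_lateral", "jsn_concentric", "sclerosis", "cysts"),
                 function(cl) mean(binary_feature(cohort$readings, cl, 1)))
  expect_equal(names(which.max(prev)), "osteo_lat_acetabular")
})

test_that("cohort tables join one-to-one and validate end to end", {
  cohort <- generate_cohort(default_sim_config(n = 100, seed = 8))
  ids <- cohort$landmarks$ids
  expect_identical(cohort$covariates$image_id, ids)
  expect_identical(cohort$readings$image_id, ids)
  expect_identical(cohort$pain$image_id, ids)
  expect_equal(nrow(cohort$true_scores), 100L)
  # readings pass validation, pains construct
  expect_silent(croft_grade(cohort$readings))
  expect_silent(pain_outcomes(cohort$pain))
})

test_that("fitting recovers the planted subspace and mode SDs", {
  # landmark noise at 20% of the smallest planted loading SD
  cfg <- default_sim_config(n = 1000, seed = 42, landmark_noise_sd = 0.4)
  sh <- sample_shapes(cfg)
  model <- fit_shape_model(gpa(sh$landmarks), k = 4)
  planted <- fields_in_model_frame(sh$fields$fields, sh$template, model)
  ang <- principal_angles(planted, model$eigenvectors)
  expect_lt(max(ang), 5)
  # eigenvalue SDs, rescaled by the template's centroid size, match planted
  cs <- sqrt(sum(scale(xy_to_shape(sh$template$points), scale = FALSE)^2))
  sds_fit <- sqrt(model$eigenvalues) * cs
  expect_lt(max(abs(sds_fit - cfg$mode_sds) / cfg$mode_sds), 0.10)
})

test_that("the planted causal effect survives the full pipeline", {
  set.seed(71)
  cfg <- default_sim_config(n = 4000, seed = 12, landmark_noise_sd = 0.4)
  cohort <- generate_cohort(cfg)
  model <- fit_shape_model(gpa(cohort$landmarks), k = 4)
  scores <- score_shapes(model, gpa(cohort$landmarks))
  outcomes <- build_outcome_table(cohort$readings, cohort$pain)
  # identify the fitted mode best aligned with the planted pincer field
  planted <- fields_in_model_frame(cohort$fields$fields, cohort$template, model)
  align <- planted %*% t(model$eigenvectors)
  pincer_mode <- which.max(abs(align["pincer_like", ]))
  sgn <- sign(align["pincer_like", pincer_mode])
  res <- fit_logistic(outcomes$rhoa_croft2, scores[[paste0("mode", pincer_mode)]],
                      covariates = cohort$covariates)
  or_aligned <- res$or_per_sd^sgn   # orient to the planted field's direction
  # planted OR 1.23 per SD: the Wald CI should cover it
  ci <- sort(c(res$ci_low, res$ci_high)^sgn)
  expect_gt(1.23, ci[1])
  expect_lt(1.23, ci[2])
  expect_gt(or_aligned, 1)
})
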