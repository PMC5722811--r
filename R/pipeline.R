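# End-to-end pipeline: simulate -> align -> fit -> score -> QC -> outcomes
# -> associations -> report bundle.

#' Default pipeline configuration
#'
#' Every analysis threshold surfaces as a named key with its standard value
#' as default: Croft cut-offs 2 (primary) and 3 (severe), osteophyte grade
#' cut-offs 1 and 2, the 4 SD outlier-review threshold, the 3-pixel operator
#' accuracy threshold, and the 0.05/10 = 0.005 Bonferroni-corrected
#' significance level for ten modes.
#'
#' @param out_dir output directory for the report bundle.
#' @param n_shapes synthetic cohort size (named to stay clear of YAML 1.1,
#'   which resolves a bare `n` key to a boolean).
#' @param k number of shape modes to retain.
#' @param seed integer seed.
#' @param ... overrides for any other key.
#' @return a named list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("hipshape_run_"),
                                    n_shapes = 500L, k = 10L, seed = 20260101L, ...) {
  cfg <- list(out_dir = out_dir, n_shapes = as.integer(n_shapes), k = as.integer(k),
              seed = as.integer(seed),
              croft_threshold = 2L, severe_croft_threshold = 3L,
              osteophyte_grades = c(1L, 2L),
              outlier_sd = 4, qc_threshold_px = 3, qc_images = 100L,
              alpha = 0.05, gpa_tol = 1e-8, gpa_max_iter = 100L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys present in the file override [default_pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_pipeline_config()
  cfg[names(user)] <- user
  cfg
}

#' Write a +/-2 SD mode-shape overlay as SVG
#'
#' Dashed outline = +`sd` SD, solid outline = -`sd` SD, light outline =
#' mean, drawn in the model's aligned frame.
#'
#' @param model a `shape_model`.
#' @param mode mode index.
#' @param path output `.svg` path.
#' @param sd SD offset (default 2).
#' @return `path`, invisibly.
#' @export
write_mode_svg <- function(model, mode, path, sd = 2) {
  at <- function(s) {
    v <- numeric(model$k); v[mode] <- s
    shape_to_xy(reconstruct(model, v))
  }
  shapes <- list(mean = at(0), plus = at(sd), minus = at(-sd))
  all_pts <- do.call(rbind, shapes)
  # scale the unit-size aligned frame up to a 400 px canvas
  rng <- apply(all_pts, 2L, range)
  span <- max(rng[2, ] - rng[1, ])
  px <- function(m) {
    s <- sweep(m, 2L, rng[1, ])
    20 + 360 * s / span
  }
  poly <- function(m, style) {
    pts <- paste(sprintf("%.2f,%.2f", m[, 1], m[, 2]), collapse = " ")
    sprintf('<polyline points="%s" fill="none" %s/>', pts, style)
  }
  lines <- c(
    '<svg xmlns="http://www.w3.org/2000/svg" width="400" height="400" viewBox="0 0 400 400">',
    sprintf('<title>Mode %d at +/-%g SD</title>', mode, sd),
    poly(px(shapes$mean), 'stroke="#bbbbbb" stroke-width="1"'),
    poly(px(shapes$plus), 'stroke="#000000" stroke-width="1.5" stroke-dasharray="6,4"'),
    poly(px(shapes$minus), 'stroke="#000000" stroke-width="1.5"'),
    "</svg>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write +/-2 SD mode outlines as a polyline CSV
#'
#' @param model a `shape_model`.
#' @param modes mode indices.
#' @param path output CSV path.
#' @param sd SD offset.
#' @return `path`, invisibly.
#' @export
write_mode_outlines <- function(model, modes, path, sd = 2) {
  rows <- do.call(rbind, lapply(modes, function(mode) {
    do.call(rbind, lapply(c(-sd, 0, sd), function(s) {
      v <- numeric(model$k); v[mode] <- s
      m <- shape_to_xy(reconstruct(model, v))
      data.frame(mode = mode, sd = s, point_index = seq_len(nrow(m)) - 1L,
                 x = m[, 1], y = m[, 2])
    }))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages: generate cohort; write and re-read the landmark CSV (exercising
#' the I/O contract); generalized Procrustes alignment; shape-model fit and
#' scoring; outlier flagging; simulated two-operator placement QC; outcome
#' construction; the association battery; and the report bundle
#' (`results.csv`, `model.json`, `scores.csv`, mode SVGs and outline CSV,
#' `run_log.txt`). Reruns with the same config reproduce `results.csv`
#' byte-identically.
#'
#' @param config list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @return invisible list with the fitted objects and bundle paths.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- c(sprintf("hipshape run, seed %d, n %d, k %d",
                         config$seed, config$n_shapes, config$k),
                 sprintf("R %s, hipshape %s", getRversion(),
                         as.character(utils::packageVersion("hipshape"))))
  stage <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%6.2fs] %s",
                                       as.numeric(Sys.time() - t0, units = "secs"), msg))
  }

  cohort <- generate_cohort(default_sim_config(n = config$n_shapes, seed = config$seed))
  stage(sprintf("simulated cohort: %d shapes, P = %d", config$n_shapes, cohort$config$P))

  lm_path <- file.path(config$out_dir, "landmarks.csv")
  write_landmarks(cohort$landmarks, lm_path)
  lms <- read_landmarks(lm_path, P = cohort$config$P)
  stage(sprintf("landmark I/O round trip: %d configurations", length(lms)))

  aligned <- gpa(lms, tol = config$gpa_tol, max_iter = config$gpa_max_iter)
  stage(sprintf("GPA converged in %d iterations", aligned$iterations))

  model <- fit_shape_model(aligned, k = config$k)
  write_shape_model(model, file.path(config$out_dir, "model.json"),
                    seed = config$seed)
  stage(sprintf("shape model: top %d modes explain %.1f%% of variance",
                model$k, variance_explained(model)))

  scores <- score_shapes(model, aligned)
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  flagged <- flag_outliers(scores, threshold = config$outlier_sd)
  stage(sprintf("scored %d shapes; %d (image, mode) pairs beyond %g SD flagged for review",
                nrow(scores), nrow(flagged), config$outlier_sd))

  qc <- simulate_operator_qc(cohort, n_images = min(config$qc_images, config$n_shapes),
                             seed = config$seed + 7L,
                             threshold = config$qc_threshold_px)
  stage(sprintf("operator QC on %d images: %d/%d operators within %g px",
                min(config$qc_images, config$n_shapes), sum(qc$pass), nrow(qc),
                config$qc_threshold_px))

  outcomes <- build_outcome_table(cohort$readings, cohort$pain)
  stage(sprintf("outcomes: RHOA prevalence %.1f%% (Croft >= %d)",
                100 * mean(outcomes$rhoa_croft2), config$croft_threshold))

  battery <- run_association_battery(scores, outcomes, cohort$covariates,
                                     modes = seq_len(config$k),
                                     alpha = config$alpha)
  utils::write.csv(battery, file.path(config$out_dir, "results.csv"),
                   row.names = FALSE)
  stage(sprintf("association battery: %d rows, %d significant at p < %.4g",
                nrow(battery), sum(battery$significant),
                bonferroni_threshold(config$alpha, config$k)))

  show_modes <- seq_len(min(3L, config$k))
  for (mode in show_modes)
    write_mode_svg(model, mode, file.path(config$out_dir, sprintf("mode_%d.svg", mode)))
  write_mode_outlines(model, show_modes,
                      file.path(config$out_dir, "mode_outlines.csv"))
  stage("wrote mode-shape SVGs and outline CSV")

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(config = config, cohort = cohort, aligned = aligned,
                 model = model, scores = scores, flagged = flagged, qc = qc,
                 outcomes = outcomes, battery = battery,
                 paths = list(
                   landmarks = lm_path,
                   model = file.path(config$out_dir, "model.json"),
                   scores = file.path(config$out_dir, "scores.csv"),
                   results = file.path(config$out_dir, "results.csv"),
                   log = file.path(config$out_dir, "run_log.txt"))))
}

#' Simulate a two-operator placement study and run QC
#'
#' Re-places each landmark of the first `n_images` cohort images by two
#' simulated operators (independent 1 px placement noise around the true
#' position) and returns the [qc_report()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param n_images images in the placement study.
#' @param seed integer seed.
#' @param threshold acceptance threshold in pixels.
#' @param operator_noise_sd per-coordinate placement noise SD per operator.
#' @return the [qc_report()] data frame.
#' @export
simulate_operator_qc <- function(cohort, n_images = 100L, seed = 1L,
                                 threshold = 3, operator_noise_sd = 1) {
  set.seed(seed)
  P <- cohort$config$P
  ids <- cohort$landmarks$ids[seq_len(n_images)]
  base <- cohort$landmarks$coords[seq_len(n_images), , drop = FALSE]
  one_op <- function(op) {
    noisy <- base + matrix(stats::rnorm(length(base), 0, operator_noise_sd),
                           nrow(base))
    data.frame(
      image_id = rep(ids, each = P), operator = op,
      point_index = rep(0:(P - 1L), times = n_images),
      x = as.vector(t(noisy[, seq_len(P), drop = FALSE])),
      y = as.vector(t(noisy[, P + seq_len(P), drop = FALSE])),
      stringsAsFactors = FALSE
    )
  }
  placements <- rbind(one_op("op_A"), one_op("op_B"))
  qc_report(placements, threshold = threshold)
}
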