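# Synthetic cohort generator.
#
# Emulates an elderly-male cohort of right-hip DXA landmark configurations
# with planted, labelled deformation fields (pincer-like acetabular
# over-coverage, cam-like head-neck asphericity, and nuisance fields), plus
# covariates, radiographic component grades and pain outcomes generated from
# known logistic / proportional-odds models. Ground truth (fields, loadings,
# intercepts, effect sizes) is retained so every downstream stage can be
# checked against it.
#
# All geometry is in the raster pixel frame (origin top-left, y down),
# right-sided: lateral structures at larger x.

IMG_H <- 600  # canvas height used to flip the construction frame to raster

#' Build the 58-point right-hip template
#'
#' A stylized right-hip outline in the raster pixel frame: a superior
#' acetabular arc (one medial "eyebrow" key point, two lateral key points on
#' the outer acetabular edge), a circular-arc femoral head, the superior
#' head-neck junction running to the greater trochanter, lateral and medial
#' shaft edges, a lesser-trochanter bump and the inferior neck (calcar)
#' returning to the medial head. Deterministic for a fixed P.
#'
#' @param P number of points (default 58, minimum 20).
#' @return An object of class `hip_template`: `P`, `points` (P x 2 matrix,
#'   raster frame), `roles` (`"key"`/`"intermediate"` per point),
#'   `key_points` (named indices), `segments` (named list of index vectors
#'   partitioning `1..P`), `head_center`, `head_radius`.
#' @export
make_hip_template <- function(P = 58L) {
  P <- as.integer(P)
  if (P < 20L) stop("P too small to allocate all template segments (need >= 20)",
                    call. = FALSE)
  # allocate the 8 contour segments proportionally to the P = 58 reference
  ref_counts <- c(acetabulum = 10L, femoral_head = 14L, superior_neck = 6L,
                  greater_trochanter = 6L, lateral_shaft = 5L,
                  medial_shaft = 5L, lesser_trochanter = 5L, inferior_neck = 7L)
  if (P == 58L) {
    counts <- ref_counts
  } else {
    raw <- P * ref_counts / sum(ref_counts)
    counts <- pmax(floor(raw), 2L)   # keep names: first argument wins
    # largest-remainder top-up to sum exactly to P
    while (sum(counts) < P) {
      i <- which.max(raw - counts)
      counts[i] <- counts[i] + 1L
    }
    while (sum(counts) > P) {
      i <- which.max(counts - raw)
      counts[i] <- counts[i] - 1L
    }
  }
  C <- c(300, 330)   # femoral head center, construction frame (y up)
  r <- 75            # head radius
  deg <- function(a) a * pi / 180
  arc <- function(center, radius, a0, a1, n)
    cbind(center[1] + radius * cos(deg(seq(a0, a1, length.out = n))),
          center[2] + radius * sin(deg(seq(a0, a1, length.out = n))))
  # quadratic Bezier for smooth non-circular stretches
  bez <- function(p0, p1, p2, n) {
    t <- seq(0, 1, length.out = n)
    cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
          (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
  }
  n <- counts
  # 1. acetabular arc: medial eyebrow end -> lateral edge, radius 95;
  #    final point sits further out on the acetabular rim (2nd lateral key)
  acet <- rbind(arc(C, 95, 150, 50, n[["acetabulum"]] - 1L),
                C + 103 * c(cos(deg(42)), sin(deg(42))))
  # 2. femoral head arc: medial head over the top to the lateral head
  head <- arc(C, r, 165, 20, n[["femoral_head"]])
  # 3. superior head-neck junction to greater trochanter tip (concave dip)
  hn0 <- C + r * c(cos(deg(20)), sin(deg(20)))
  gt_tip <- c(440, 380)
  sneck <- bez(hn0, c(405, 335), gt_tip, n[["superior_neck"]] + 1L)[-1L, , drop = FALSE]
  # 4. greater trochanter lateral contour descending
  gtro <- bez(c(448, 360), c(458, 280), c(446, 185), n[["greater_trochanter"]])
  # 5. lateral shaft edge down to the image border
  lsh <- cbind(seq(444, 440, length.out = n[["lateral_shaft"]]),
               seq(150, 10, length.out = n[["lateral_shaft"]]))
  # 6. medial shaft edge ascending
  msh <- cbind(seq(385, 388, length.out = n[["medial_shaft"]]),
               seq(10, 185, length.out = n[["medial_shaft"]]))
  # 7. lesser trochanter bump on the medial edge
  ltro <- bez(c(383, 195), c(358, 222), c(382, 252), n[["lesser_trochanter"]])
  # 8. inferior neck / calcar ascending to the inferior-medial head
  calcar_end <- C + r * c(cos(deg(195)), sin(deg(195)))
  calc <- bez(c(384, 262), c(330, 270), calcar_end, n[["inferior_neck"]])
  pts_up <- rbind(acet, head, sneck, gtro, lsh, msh, ltro, calc)
  stopifnot(nrow(pts_up) == P)
  pts <- cbind(x = pts_up[, 1], y = IMG_H - pts_up[, 2])   # flip to raster
  ends <- cumsum(n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  segments <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(segments) <- names(n)
  # key points: anatomical reference loci
  head_top <- segments$femoral_head[which.max(pts_up[segments$femoral_head, 2])]
  key_points <- c(
    medial_acetabular = segments$acetabulum[1L],
    lateral_acetabular_1 = segments$acetabulum[length(segments$acetabulum) - 1L],
    lateral_acetabular_2 = segments$acetabulum[length(segments$acetabulum)],
    femoral_head = head_top,
    femoral_neck = segments$superior_neck[1L],
    greater_trochanter = segments$superior_neck[length(segments$superior_neck)],
    lesser_trochanter = segments$lesser_trochanter[ceiling(length(segments$lesser_trochanter) / 2)]
  )
  roles <- rep("intermediate", P)
  roles[key_points] <- "key"
  structure(list(P = P, points = pts, roles = roles, key_points = key_points,
                 segments = segments,
                 head_center = c(C[1], IMG_H - C[2]), head_radius = r),
            class = "hip_template")
}

#' @export
print.hip_template <- function(x, ...) {
  cat(sprintf("<hip_template> P = %d points, %d key point(s), %d segment(s)\n",
              x$P, sum(x$roles == "key"), length(x$segments)))
  invisible(x)
}

#' Serialize a template to JSON
#' @param template a `hip_template`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_template <- function(template, path) {
  jsonlite::write_json(
    list(P = template$P, points = template$points, roles = template$roles,
         key_points = as.list(template$key_points),
         segments = template$segments, head_center = template$head_center,
         head_radius = template$head_radius),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a template from JSON
#' @param path path written by [write_template()].
#' @return a `hip_template`.
#' @export
read_template <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(P = as.integer(o$P),
                 points = matrix(unlist(o$points), ncol = 2,
                                 dimnames = list(NULL, c("x", "y"))),
                 roles = o$roles, key_points = unlist(o$key_points),
                 segments = lapply(o$segments, as.integer),
                 head_center = as.numeric(o$head_center),
                 head_radius = o$head_radius),
            class = "hip_template")
}

# similarity tangent directions at a configuration (translation x/y,
# rotation, scale), as orthonormal 2P vectors
similarity_tangent_basis <- function(v) {
  P <- length(v) / 2L
  ctr <- centroid_xy(v)
  vc <- v - rep(ctr, each = P)
  x <- vc[seq_len(P)]; y <- vc[P + seq_len(P)]
  B <- cbind(c(rep(1, P), rep(0, P)),          # translate x
             c(rep(0, P), rep(1, P)),          # translate y
             c(-y, x),                          # rotate
             vc)                                # scale
  qr.Q(qr(B))
}

#' Planted deformation fields for the synthetic generator
#'
#' Constructs labelled displacement fields on the template:
#' * `pincer_like` — the lateral acetabular rim extends laterally and
#'   inferiorly, increasing coverage of the femoral head;
#' * `cam_like` — radial outward displacement at the superior head-neck
#'   junction (asphericity where cam lesions form); zero elsewhere in its
#'   raw form;
#' * `nuisance_ltroch` — lesser-trochanter prominence;
#' * `nuisance_nsa` — a small rotation of the head-neck block about the neck
#'   base, mimicking neck-shaft-angle variation.
#'
#' Raw fields are projected off the similarity tangent space at the template
#' (so planted variation is not absorbed by Procrustes alignment) and then
#' Gram-Schmidt orthonormalized in the order above.
#'
#' @param template a [make_hip_template()] object.
#' @return list with `fields` (4 x 2P orthonormal rows), `labels`,
#'   `raw` (4 x 2P pre-orthogonalization fields), `support` (list of point
#'   indices where each raw field is nonzero).
#' @export
make_deformation_fields <- function(template) {
  P <- template$P
  pts <- template$points
  tv <- xy_to_shape(pts)
  C <- template$head_center
  seg <- template$segments
  zero <- function() numeric(2L * P)
  set_disp <- function(f, idx, dx, dy) {
    f[idx] <- dx; f[P + idx] <- dy; f
  }
  # pincer: last 4 acetabular points (incl. both lateral keys) move
  # laterally (+x) and inferiorly (+y, raster frame), ramping to the rim
  ac <- seg$acetabulum
  idx_p <- ac[seq(max(1L, length(ac) - 3L), length(ac))]
  w <- seq(0.4, 1, length.out = length(idx_p))
  pincer <- set_disp(zero(), idx_p, 0.8 * w, 0.6 * w)
  # cam: radial outward from the head center at the head-neck junction
  # (last 2 head points + first 3 superior-neck points)
  hd <- seg$femoral_head; sn <- seg$superior_neck
  idx_c <- c(utils::tail(hd, 2L), utils::head(sn, 3L))
  u <- sweep(pts[idx_c, , drop = FALSE], 2L, C)
  u <- u / sqrt(rowSums(u^2))
  wc <- c(0.5, 1, 1, 0.8, 0.4)[seq_along(idx_c)]
  cam <- set_disp(zero(), idx_c, wc * u[, 1], wc * u[, 2])
  # nuisance 1: lesser trochanter prominence (medial bulge, -x)
  lt <- seg$lesser_trochanter
  wl <- sin(seq(0, pi, length.out = length(lt)))
  ltf <- set_disp(zero(), lt, -wl, 0 * wl)
  # nuisance 2: rotate head + superior neck + calcar about the neck base
  pivot <- c(415, IMG_H - 300)
  idx_r <- c(seg$femoral_head, seg$superior_neck, seg$inferior_neck)
  d <- sweep(pts[idx_r, , drop = FALSE], 2L, pivot)
  nsa <- set_disp(zero(), idx_r, -d[, 2] * 0.01, d[, 1] * 0.01)
  raw <- rbind(pincer_like = pincer, cam_like = cam,
               nuisance_ltroch = ltf, nuisance_nsa = nsa)
  support <- list(pincer_like = idx_p, cam_like = idx_c,
                  nuisance_ltroch = lt, nuisance_nsa = idx_r)
  # project off similarity tangent directions, then Gram-Schmidt
  S <- similarity_tangent_basis(tv)
  fields <- raw
  for (j in seq_len(nrow(fields)))
    fields[j, ] <- fields[j, ] - S %*% crossprod(S, fields[j, ])
  for (j in seq_len(nrow(fields))) {
    v <- fields[j, ]
    if (j > 1L)
      for (i in seq_len(j - 1L)) v <- v - sum(v * fields[i, ]) * fields[i, ]
    fields[j, ] <- v / sqrt(sum(v^2))
  }
  list(fields = fields, labels = rownames(raw), raw = raw, support = support)
}

#' Default simulation configuration
#'
#' Cohort conditions emulate the target population: n = 4100 participants
#' with readable radiographs by default; standard-normal-scaled mode
#' loadings; RHOA prevalence 7.1% (Croft >= 2) with 2.4% severe (Croft >=
#' 3); pain on internal rotation 11.4%; walking pain 20.2%; right-skewed
#' WOMAC with mean near 0.9; covariates age 72.8 (5.7) y, height 174.4
#' (6.8) cm, weight 83.6 (12.9) kg; race 90.7% white, 3.3% Asian, 3.2%
#' African American, 2.8% other. Planted effects: pincer loading raises
#' RHOA odds (OR 1.23 per SD), cam loading raises RHOA odds (OR 1.37 per
#' SD) and pain odds (OR 1.19 exam, 1.14 walking, 1.15 WOMAC per SD).
#'
#' @param n cohort size.
#' @param P landmark count.
#' @param seed integer seed governing every stage.
#' @param mode_sds raw loading SDs (pixels) for the four planted fields.
#' @param landmark_noise_sd isotropic per-coordinate landmark noise, pixels.
#' @param transform_jitter list with `scale`, `rotation_deg`, `translation`
#'   ranges for the random similarity transform applied to each shape.
#' @param prevalence_targets named targets for intercept calibration.
#' @param log_or named lists of per-field log odds ratios per SD.
#' @return a `sim_config` list.
#' @export
default_sim_config <- function(n = 4100L, P = 58L, seed = 20260101L,
                               mode_sds = c(pincer_like = 6, cam_like = 4,
                                            nuisance_ltroch = 3, nuisance_nsa = 2),
                               landmark_noise_sd = 1,
                               transform_jitter = list(scale = c(0.9, 1.1),
                                                       rotation_deg = c(-10, 10),
                                                       translation = c(-20, 20)),
                               prevalence_targets = c(rhoa = 0.071,
                                                      exam_pain = 0.114,
                                                      walking_pain = 0.202),
                               log_or = list(
                                 rhoa = c(pincer_like = log(1.23), cam_like = log(1.37),
                                          nuisance_ltroch = 0, nuisance_nsa = 0),
                                 exam_pain = c(pincer_like = 0, cam_like = log(1.19),
                                               nuisance_ltroch = 0, nuisance_nsa = 0),
                                 walking_pain = c(pincer_like = 0, cam_like = log(1.14),
                                                  nuisance_ltroch = 0, nuisance_nsa = 0),
                                 womac = c(pincer_like = 0, cam_like = log(1.15),
                                           nuisance_ltroch = 0, nuisance_nsa = 0))) {
  structure(list(n = as.integer(n), P = as.integer(P), seed = as.integer(seed),
                 mode_sds = mode_sds, landmark_noise_sd = landmark_noise_sd,
                 transform_jitter = transform_jitter,
                 prevalence_targets = prevalence_targets,
                 log_or = log_or,
                 covariate_log_or = c(age = 0.02, height = -0.01, weight = 0.01),
                 # osteophyte-only stratum among non-cases (Croft grade 1),
                 # set so the lateral acetabular osteophyte marginal lands
                 # near its 19.2% population target
                 noncase_osteophyte_rate = 0.22,
                 covariates = list(age = c(72.8, 5.7), height = c(174.4, 6.8),
                                   weight = c(83.6, 12.9),
                                   race_probs = c(white = 0.907, asian = 0.033,
                                                  african_american = 0.032,
                                                  other = 0.028)),
                 severe_fraction = 0.34),
            class = "sim_config")
}

#' Sample landmark configurations from the generative shape model
#'
#' `shape_i = template + sum_j b_ij field_j + noise`, with
#' `b_ij ~ N(0, mode_sds_j^2)` and isotropic Gaussian landmark noise, then a
#' random similarity transform (scale, rotation, translation) per shape.
#'
#' @param config a [default_sim_config()] list.
#' @param template optional precomputed template (built from `config$P`
#'   otherwise).
#' @param fields optional precomputed [make_deformation_fields()] result.
#' @return list with `landmarks` (a [landmark_set()]), `true_scores`
#'   (n x 4 raw loadings), `template`, `fields`.
#' @export
sample_shapes <- function(config, template = NULL, fields = NULL) {
  if (is.null(template)) template <- make_hip_template(config$P)
  if (is.null(fields)) fields <- make_deformation_fields(template)
  set.seed(config$seed + 1L)
  n <- config$n
  P <- config$P
  tv <- xy_to_shape(template$points)
  k <- nrow(fields$fields)
  b <- matrix(stats::rnorm(n * k), n, k) %*% diag(config$mode_sds, k)
  colnames(b) <- fields$labels
  shapes <- matrix(rep(tv, each = n), n) + b %*% fields$fields
  if (config$landmark_noise_sd > 0)
    shapes <- shapes + matrix(stats::rnorm(n * 2L * P, 0, config$landmark_noise_sd), n)
  tj <- config$transform_jitter
  sc <- stats::runif(n, tj$scale[1], tj$scale[2])
  th <- stats::runif(n, tj$rotation_deg[1], tj$rotation_deg[2]) * pi / 180
  tx <- stats::runif(n, tj$translation[1], tj$translation[2])
  ty <- stats::runif(n, tj$translation[1], tj$translation[2])
  for (i in seq_len(n)) {
    m <- shape_to_xy(shapes[i, ])
    R <- matrix(c(cos(th[i]), sin(th[i]), -sin(th[i]), cos(th[i])), 2L)
    m2 <- sc[i] * m %*% t(R)
    shapes[i, ] <- xy_to_shape(sweep(m2, 2L, -c(tx[i], ty[i])))
  }
  ids <- sprintf("img_%04d", seq_len(n))
  rownames(shapes) <- ids
  rownames(b) <- ids
  list(landmarks = landmark_set(shapes, ids = ids, side = "right"),
       true_scores = b, template = template, fields = fields)
}

#' Sample the covariate table
#'
#' @param config a [default_sim_config()] list.
#' @return data frame: `image_id`, `age`, `height`, `weight`, `race`.
#' @export
sample_covariates <- function(config) {
  set.seed(config$seed + 2L)
  n <- config$n
  cv <- config$covariates
  data.frame(
    image_id = sprintf("img_%04d", seq_len(n)),
    age = stats::rnorm(n, cv$age[1], cv$age[2]),
    height = stats::rnorm(n, cv$height[1], cv$height[2]),
    weight = stats::rnorm(n, cv$weight[1], cv$weight[2]),
    race = sample(names(cv$race_probs), n, replace = TRUE, prob = cv$race_probs),
    stringsAsFactors = FALSE
  )
}

# calibrate the intercept of a logistic model so the mean predicted
# probability over the realized linear predictors hits the target
calibrate_intercept <- function(eta, target) {
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - target,
                 interval = c(-30, 30), tol = 1e-10)$root
}

#' Plant radiographic readings and pain outcomes with known effect sizes
#'
#' Case status for each outcome follows a logistic model on the
#' standardised planted loadings and centered covariates, with the
#' intercept calibrated by root-finding so the cohort's expected prevalence
#' equals its target. RHOA cases receive component grades that guarantee
#' Croft >= 2 (JSN only, or two/three of the four feature classes, always
#' including osteophytes or JSN); a configured fraction of cases receives
#' the grade-3+ patterns, reproducing the moderate/severe split. Non-cases
#' are grade-0 dominant, with an osteophyte-only stratum (Croft 1) so that
#' lateral acetabular osteophytes are the most common individual feature.
#' WOMAC is drawn from a proportional-odds model over 0-20 with a
#' right-skewed baseline (mean near 0.9).
#'
#' @param true_scores n x 4 raw loading matrix from [sample_shapes()].
#' @param covariates data frame from [sample_covariates()].
#' @param config a [default_sim_config()] list.
#' @return list with `readings`, `pain` (data frames keyed by `image_id`)
#'   and `truth` (calibrated intercepts and the per-outcome linear
#'   predictors).
#' @export
plant_outcomes <- function(true_scores, covariates, config) {
  set.seed(config$seed + 3L)
  n <- nrow(true_scores)
  z <- scale(true_scores)   # SD units using the cohort's own SD
  cvz <- cbind(age = covariates$age - mean(covariates$age),
               height = covariates$height - mean(covariates$height),
               weight = covariates$weight - mean(covariates$weight))
  cov_eta <- as.vector(cvz %*% config$covariate_log_or[colnames(cvz)])
  eta_of <- function(outcome)
    as.vector(z %*% config$log_or[[outcome]][colnames(z)]) + cov_eta
  intercepts <- numeric(0)
  draw_cases <- function(outcome) {
    eta <- eta_of(outcome)
    a <- calibrate_intercept(eta, config$prevalence_targets[[outcome]])
    intercepts[[outcome]] <<- a
    achieved <- mean(stats::plogis(a + eta))
    if (abs(achieved - config$prevalence_targets[[outcome]]) > 0.02)
      stop("prevalence calibration failed for ", outcome, call. = FALSE)
    stats::runif(n) < stats::plogis(a + eta)
  }
  rhoa <- draw_cases("rhoa")
  exam <- draw_cases("exam_pain")
  walk <- draw_cases("walking_pain")

  readings <- data.frame(image_id = sprintf("img_%04d", seq_len(n)))
  for (col in names(GRADE_RANGES)) readings[[col]] <- 0L
  readings$chondrocalcinosis <- stats::runif(n) < 0.0022

  draw_sites <- function(i, cols, probs, grades, gprobs) {
    on <- stats::runif(length(cols)) < probs
    if (!any(on)) on[1L] <- TRUE
    for (s in which(on))
      readings[i, cols[s]] <<- sample(grades, 1L, prob = gprobs)
  }
  osteo_site_p <- c(0.75, 0.28, 0.28, 0.18)   # lateral acetabular dominant
  jsn_site_p <- c(0.75, 0.35, 0.25)           # medial dominant
  add_osteo <- function(i) draw_sites(i, OSTEO_COLS, osteo_site_p, 1:2, c(0.8, 0.2))
  add_jsn <- function(i) draw_sites(i, c("jsn_medial", "jsn_lateral", "jsn_concentric"),
                                    jsn_site_p, 1:3, c(0.6, 0.3, 0.1))
  add_scler <- function(i) readings$sclerosis[i] <<- sample(1:2, 1L, prob = c(0.8, 0.2))
  add_cysts <- function(i) readings$cysts[i] <<- 1L

  sf <- config$severe_fraction
  pattern_p <- c(jsn_only = 1 - sf, two = 0.59 * sf, three = 0.29 * sf,
                 deform = 0.12 * sf)
  for (i in which(rhoa)) {
    pat <- sample(names(pattern_p), 1L, prob = pattern_p)
    if (pat == "jsn_only") {
      add_jsn(i)
    } else if (pat == "two") {
      pair <- sample(c("oj", "os", "js", "oc"), 1L, prob = c(0.6, 0.2, 0.15, 0.05))
      if (pair %in% c("oj", "os", "oc")) add_osteo(i)
      if (pair %in% c("oj", "js")) add_jsn(i)
      if (pair %in% c("os", "js")) add_scler(i)
      if (pair == "oc") add_cysts(i)
    } else {                                   # three of four (+/- deformity)
      trip <- sample(c("ojs", "ojc", "osc", "jsc"), 1L,
                     prob = c(0.7, 0.15, 0.1, 0.05))
      if (grepl("o", trip)) add_osteo(i)
      if (grepl("j", trip)) add_jsn(i)
      if (grepl("s", trip)) add_scler(i)
      if (grepl("c", trip)) add_cysts(i)
      if (pat == "deform") readings$head_deformity[i] <- sample(1:2, 1L, prob = c(0.8, 0.2))
    }
  }
  # non-cases: osteophyte-only stratum (Croft grade 1)
  nc_osteo <- which(!rhoa & stats::runif(n) < config$noncase_osteophyte_rate)
  for (i in nc_osteo) add_osteo(i)

  # walking pain raw 0-4 consistent with its binary (>= 1) definition
  walk_raw <- integer(n)
  walk_raw[walk] <- sample(1:4, sum(walk), replace = TRUE,
                           prob = c(0.5, 0.3, 0.15, 0.05))
  # WOMAC: proportional odds over 0..20, right-skewed baseline, mean ~ 0.9
  base_p <- stats::dnbinom(0:20, size = 0.35, mu = 0.9)
  base_p <- base_p / sum(base_p)
  theta <- stats::qlogis(pmin(cumsum(base_p)[1:20], 1 - 1e-12))
  eta_w <- eta_of("womac")
  cum_p <- stats::plogis(outer(eta_w, theta, function(e, th) th - e))
  u <- stats::runif(n)
  womac <- rowSums(u > cbind(cum_p, 1)) # counts thresholds passed -> 0..20
  pain <- data.frame(image_id = readings$image_id,
                     pain_internal_rotation = as.integer(exam),
                     walking_pain_raw = walk_raw,
                     womac = as.integer(womac),
                     stringsAsFactors = FALSE)
  list(readings = readings, pain = pain,
       truth = list(intercepts = intercepts, rhoa = rhoa,
                    exam_pain = exam, walking_pain = walk))
}

#' Generate a complete synthetic cohort
#'
#' Composition of [sample_shapes()], [sample_covariates()] and
#' [plant_outcomes()] under a single seed (each stage derives its own
#' stream from `config$seed` so stages are independently reproducible).
#'
#' @param config a [default_sim_config()] list (or arguments forwarded to
#'   it via `...`).
#' @param ... used when `config` is missing: forwarded to
#'   [default_sim_config()].
#' @return An object of class `synthetic_cohort`: `landmarks`,
#'   `true_scores`, `covariates`, `readings`, `pain`, `template`, `fields`,
#'   `truth`, `config`.
#' @export
generate_cohort <- function(config = NULL, ...) {
  if (is.null(config)) config <- default_sim_config(...)
  sh <- sample_shapes(config)
  cv <- sample_covariates(config)
  oc <- plant_outcomes(sh$true_scores, cv, config)
  structure(list(landmarks = sh$landmarks, true_scores = sh$true_scores,
                 covariates = cv, readings = oc$readings, pain = oc$pain,
                 template = sh$template, fields = sh$fields,
                 truth = oc$truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, P = %d, seed = %d\n",
              x$config$n, x$config$P, x$config$seed))
  invisible(x)
}

#' Acetabular coverage arc of a configuration
#'
#' The angle (degrees) subtended at the femoral head center between the
#' medial acetabular key point and the outermost lateral acetabular key
#' point. A pincer-type displacement extends the lateral rim laterally and
#' inferiorly, so coverage increases with positive pincer loading.
#'
#' @param shape 2P coordinate vector (template frame).
#' @param template the matching `hip_template`.
#' @return angle in degrees.
#' @export
coverage_arc <- function(shape, template) {
  m <- shape_to_xy(shape)
  C <- template$head_center
  a1 <- m[template$key_points[["medial_acetabular"]], ]
  a2 <- m[template$key_points[["lateral_acetabular_2"]], ]
  v1 <- a1 - C; v2 <- a2 - C
  acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
}

#' Express planted deformation fields in a fitted model's frame
#'
#' The orientation of a generalized-Procrustes solution is arbitrary (it
#' follows the initial reference), so planted fields defined in the template
#' frame must be rotated into the fitted frame before being compared with
#' eigenvectors. This rotates each field by the optimal rotation carrying
#' the template onto the model's mean shape; rotation preserves
#' orthonormality and principal angles are then well defined.
#'
#' @param fields m x 2P matrix of fields in the template frame.
#' @param template the `hip_template` the fields were built on.
#' @param model a fitted `shape_model`.
#' @return m x 2P matrix of rotated fields.
#' @export
fields_in_model_frame <- function(fields, template, model) {
  tv <- xy_to_shape(template$points)
  th <- align_pair(tv, model$mean_shape)$transform$rotation
  P <- ncol(fields) / 2L
  rot1 <- function(f) {
    x <- f[seq_len(P)]; y <- f[P + seq_len(P)]
    c(cos(th) * x - sin(th) * y, sin(th) * x + cos(th) * y)
  }
  out <- t(apply(fields, 1L, rot1))
  dimnames(out) <- dimnames(fields)
  out
}

#' Principal angles between two row-orthonormal bases
#'
#' @param A,B matrices with orthonormal rows spanning the subspaces.
#' @return angles in degrees, one per dimension of the smaller subspace.
#' @export
principal_angles <- function(A, B) {
  sv <- svd(A %*% t(B))$d
  acos(pmin(pmax(sv, -1), 1)) * 180 / pi
}
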