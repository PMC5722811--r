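# Covariate-adjusted association models: odds ratio per SD of a shape mode.
#
# Binary outcomes use maximum-likelihood logistic regression (stats::glm);
# ordinal outcomes (WOMAC) use the proportional-odds model (MASS::polr) with
# a common odds ratio across thresholds. Confidence intervals are Wald
# intervals on the log-odds scale, exp(beta +/- 1.96 SE), with two-sided
# Wald p-values. Adjustment is for age, height, weight and race (indicator
# contrasts against "white", the largest category). Models are complete-case
# per outcome.

covariate_frame <- function(covariates, ids) {
  stopifnot(all(c("age", "height", "weight", "race") %in% names(covariates)))
  cv <- covariates[match(ids, covariates$image_id), , drop = FALSE]
  race <- as.character(cv$race)
  lev <- intersect(c("white", sort(setdiff(unique(race), "white"))), unique(race))
  out <- data.frame(age = cv$age, height = cv$height, weight = cv$weight)
  if (length(lev) > 1L) out$race <- factor(race, levels = lev)
  out
}

# glm emits warnings for the exact conditions fit_logistic diagnoses itself
# (separation, non-convergence); muffle those so callers see one clean error
quiet_glm <- function(formula, data) {
  withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically|did not converge",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

wald_result <- function(beta, se, exposure, outcome, model, n_used, adjusted) {
  or <- exp(beta)
  z <- beta / se
  data.frame(
    exposure = exposure, outcome = outcome, model = model,
    or_per_sd = or,
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    n_used = n_used, adjusted = adjusted,
    stringsAsFactors = FALSE
  )
}

#' Logistic regression of a binary outcome on a mode score
#'
#' Maximum-likelihood logistic fit; the reported odds ratio is per unit of
#' the exposure, i.e. per SD when the exposure is a standardised mode score.
#' Detects (quasi-)separation by non-convergence or a diverging coefficient
#' and raises an error naming the exposure rather than reporting a
#' meaningless Wald interval.
#'
#' @param outcome logical/0-1 vector.
#' @param exposure numeric vector (SD units).
#' @param covariates optional data frame with `image_id`, `age`, `height`,
#'   `weight`, `race` (adjusted model) or NULL (unadjusted).
#' @param ids participant ids aligning outcome/exposure rows to covariates.
#' @param exposure_name,outcome_name labels carried into the result row.
#' @return one-row data frame: `exposure`, `outcome`, `model`, `or_per_sd`,
#'   `ci_low`, `ci_high`, `p`, `n_used`, `adjusted`.
#' @export
fit_logistic <- function(outcome, exposure, covariates = NULL, ids = NULL,
                         exposure_name = "exposure", outcome_name = "outcome") {
  y <- as.numeric(outcome)
  dat <- data.frame(y = y, x = as.numeric(exposure))
  if (!is.null(covariates)) {
    if (is.null(ids)) ids <- covariates$image_id
    dat <- cbind(dat, covariate_frame(covariates, ids))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (length(unique(dat$y)) < 2L)
    stop("outcome '", outcome_name, "' has a single class", call. = FALSE)
  fit <- quiet_glm(y ~ ., dat)
  beta <- stats::coef(fit)[["x"]]
  if (!fit$converged || abs(beta) > 10)
    stop("separation or non-convergence for exposure '", exposure_name, "'",
         call. = FALSE)
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  wald_result(beta, se, exposure_name, outcome_name, "logistic",
              nrow(dat), !is.null(covariates))
}

#' Proportional-odds regression of an ordinal outcome on a mode score
#'
#' Proportional-odds (ordinal logistic) maximum-likelihood fit with a common
#' odds ratio across all thresholds. Sparse top categories are collapsed
#' upward until every modelled category holds at least `min_per_level`
#' observations (the 0-20 WOMAC tail is sparse); a two-level outcome reduces
#' exactly to binary logistic regression.
#'
#' @param outcome integer-valued ordinal vector (e.g. WOMAC 0-20).
#' @param exposure numeric vector (SD units).
#' @param covariates,ids,exposure_name,outcome_name as in [fit_logistic()].
#' @param min_per_level minimum observations per modelled category.
#' @return one-row data frame as in [fit_logistic()] with `model = "ordinal"`.
#' @export
fit_ordinal <- function(outcome, exposure, covariates = NULL, ids = NULL,
                        exposure_name = "exposure", outcome_name = "outcome",
                        min_per_level = 5L) {
  dat <- data.frame(yraw = as.numeric(outcome), x = as.numeric(exposure))
  if (!is.null(covariates)) {
    if (is.null(ids)) ids <- covariates$image_id
    dat <- cbind(dat, covariate_frame(covariates, ids))
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  y <- collapse_sparse_levels(dat$yraw, min_per_level)
  if (nlevels(y) < 2L)
    stop("outcome '", outcome_name, "' has fewer than 2 levels after collapsing",
         call. = FALSE)
  dat$y <- y
  dat$yraw <- NULL
  if (nlevels(y) == 2L) {
    # one threshold: the proportional-odds likelihood coincides with binary
    # logistic regression
    dat$y <- as.integer(dat$y == levels(y)[2L])
    fit <- quiet_glm(y ~ ., dat)
    beta <- stats::coef(fit)[["x"]]
    se <- sqrt(diag(stats::vcov(fit)))[["x"]]
    return(wald_result(beta, se, exposure_name, outcome_name, "ordinal",
                       nrow(dat), !is.null(covariates)))
  }
  fit <- tryCatch(
    MASS::polr(y ~ ., data = dat, Hess = TRUE),
    error = function(e) stop("proportional-odds fit failed for exposure '",
                             exposure_name, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  beta <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  wald_result(beta, se, exposure_name, outcome_name, "ordinal",
              nrow(dat), !is.null(covariates))
}

# collapse ordered integer levels upward so each kept level has >= m obs;
# returns an ordered factor
collapse_sparse_levels <- function(y, m) {
  tab <- table(y)
  vals <- as.numeric(names(tab))
  counts <- as.integer(tab)
  # walk from the top, accumulating sparse levels into the level below
  # until each merged group holds >= m observations
  grp <- numeric(length(vals))
  acc <- 0L
  g <- vals[length(vals)]
  for (i in rev(seq_along(vals))) {
    acc <- acc + counts[i]
    grp[i] <- g
    if (acc >= m) { acc <- 0L; if (i > 1L) g <- vals[i - 1L] }
  }
  # if the bottom group ended short, merge it upward into the next group
  if (acc > 0L && length(unique(grp)) > 1L) {
    short <- grp == grp[1L]
    grp[short] <- unique(grp[!short])[1L]
  }
  mapped <- grp[match(y, vals)]
  factor(mapped, levels = sort(unique(grp)), ordered = TRUE)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` independent exposures; 0.05 over the ten retained
#' shape modes gives 0.005.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests.
#' @return per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 10L) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' Run the full mode-by-outcome association battery
#'
#' One model per (mode, outcome, adjustment) cell: logistic for binary
#' outcomes, proportional-odds for ordinal ones. Rows are flagged
#' significant at the Bonferroni threshold for the number of modes tested.
#' Per-cell model failures (e.g. separation) are recorded in an `error`
#' column rather than aborting the battery.
#'
#' @param scores data frame from [score_shapes()].
#' @param outcomes data frame from [build_outcome_table()].
#' @param covariates data frame with `image_id`, `age`, `height`, `weight`,
#'   `race`, or NULL to fit only unadjusted models.
#' @param outcome_names outcome columns to model (default: the paper-style
#'   battery — RHOA at both Croft thresholds, osteophytes at both grade
#'   cut-offs, JSN, sclerosis, the binary pains, and ordinal WOMAC).
#' @param modes integer mode indices (default 1:10).
#' @param adjusted logical settings to run (default both FALSE and TRUE;
#'   TRUE requires covariates).
#' @param alpha family-wise error rate for the significance flag.
#' @return data frame with one row per cell: battery columns plus
#'   `significant` and `error`.
#' @export
run_association_battery <- function(scores, outcomes, covariates = NULL,
                                    outcome_names = NULL, modes = 1:10,
                                    adjusted = c(FALSE, TRUE), alpha = 0.05) {
  if (is.null(outcome_names)) {
    outcome_names <- setdiff(names(outcomes), c("image_id", "croft", "womac"))
    outcome_names <- c(outcome_names, "womac")
  }
  dat <- merge(scores, outcomes, by = "image_id", sort = FALSE)
  lost <- nrow(scores) - nrow(dat)
  if (lost > 0)
    warning(sprintf("%d of %d scored images had no outcome row", lost, nrow(scores)))
  if (any(adjusted) && is.null(covariates))
    stop("adjusted models requested but no covariates supplied", call. = FALSE)
  thr <- bonferroni_threshold(alpha, length(modes))
  rows <- list()
  for (oc in outcome_names) {
    is_ordinal <- oc == "womac"
    for (mode in modes) {
      mc <- sprintf("mode%d", mode)
      for (adj in adjusted) {
        cv <- if (adj) covariates else NULL
        res <- tryCatch({
          f <- if (is_ordinal) fit_ordinal else fit_logistic
          f(dat[[oc]], dat[[mc]], covariates = cv, ids = dat$image_id,
            exposure_name = mc, outcome_name = oc)
        }, error = function(e) {
          data.frame(exposure = mc, outcome = oc,
                     model = if (is_ordinal) "ordinal" else "logistic",
                     or_per_sd = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     p = NA_real_, n_used = NA_integer_, adjusted = adj,
                     error = conditionMessage(e), stringsAsFactors = FALSE)
        })
        if (is.null(res$error)) res$error <- NA_character_
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < thr
  rownames(out) <- NULL
  out
}
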