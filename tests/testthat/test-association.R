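test_that("logistic fit matches the 2x2 closed-form odds ratio", {
  # exposed: 20 cases / 80 controls; unexposed: 10 cases / 90 controls
  y <- c(rep(1, 20), rep(0, 80), rep(1, 10), rep(0, 90))
  x <- c(rep(1, 100), rep(0, 100))
  res <- fit_logistic(y, x)
  expect_equal(res$or_per_sd, (20 * 90) / (80 * 10), tolerance = 1e-6)
  expect_equal(res$n_used, 200L)
  expect_false(res$adjusted)
})

test_that("a null exposure is well calibrated", {
  set.seed(61)
  reps <- 200
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, 0.1)
    res <- fit_logistic(y, x)
    covered[r] <- res$ci_low <= 1 && 1 <= res$ci_high
  }
  # CI covers the null in ~95% of replicates (binomial 99.9% band)
  expect_gt(mean(covered), 0.95 - 3.3 * sqrt(0.95 * 0.05 / reps))
  expect_lt(mean(covered), 0.95 + 3.3 * sqrt(0.95 * 0.05 / reps))
})

test_that("planted logistic effect log(1.25) is recovered across replicates", {
  set.seed(62)
  reps <- 200
  n <- 4000
  beta_true <- log(1.25)
  betas <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(0.07) + beta_true * z))
    betas[r] <- log(fit_logistic(y, z)$or_per_sd)
  }
  mc_se <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - beta_true), 3 * mc_se)
})

test_that("separation and single-class outcomes raise named errors", {
  x <- c(rep(-2, 30), rep(2, 30))
  y <- as.integer(x > 0)
  expect_error(suppressWarnings(fit_logistic(y, x, exposure_name = "mode7")),
               "mode7")
  expect_error(fit_logistic(rep(1, 50), rnorm(50), outcome_name = "rare"),
               "rare")
})

test_that("negating the exposure inverts the OR and preserves p", {
  set.seed(63)
  z <- rnorm(800)
  y <- rbinom(800, 1, plogis(-2 + 0.3 * z))
  a <- fit_logistic(y, z)
  b <- fit_logistic(y, -z)
  expect_equal(b$or_per_sd, 1 / a$or_per_sd, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-12)
  expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-10)
})

test_that("two-level ordinal outcome reduces to binary logistic", {
  set.seed(64)
  z <- rnorm(1500)
  y <- rbinom(1500, 1, plogis(-1 + 0.4 * z))
  lg <- fit_logistic(y, z)
  or <- fit_ordinal(y, z)
  expect_equal(or$or_per_sd, lg$or_per_sd, tolerance = 1e-6)
  expect_equal(or$p, lg$p, tolerance = 1e-5)
})

test_that("planted proportional-odds effect log(0.87) is recovered", {
  set.seed(65)
  reps <- 30
  n <- 4000
  beta_true <- log(0.87)
  theta <- qlogis(c(0.5, 0.75, 0.9, 0.97))   # K = 5 levels
  betas <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- rnorm(n)
    cum <- plogis(outer(beta_true * z, theta, function(e, th) th - e))
    y <- rowSums(runif(n) > cbind(cum, 1))
    betas[r] <- log(fit_ordinal(y, z)$or_per_sd)
  }
  mc_se <- sd(betas) / sqrt(reps)
  expect_lt(abs(mean(betas) - beta_true), 3 * mc_se)
})

test_that("ordinal p-values are uniform under the null", {
  set.seed(66)
  reps <- 200
  n <- 400
  theta <- qlogis(c(0.55, 0.8, 0.93))
  ps <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- rnorm(n)
    cum <- matrix(plogis(theta), n, 3, byrow = TRUE)
    y <- rowSums(runif(n) > cbind(cum, 1))
    ps[r] <- fit_ordinal(y, z)$p
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("sparse ordinal categories collapse to >= 5 observations each", {
  y <- c(rep(0, 50), rep(1, 30), rep(2, 10), rep(3, 3), rep(4, 1), rep(20, 1))
  f <- hipshape:::collapse_sparse_levels(y, 5L)
  expect_true(all(table(f) >= 5))
  expect_gte(nlevels(f), 3L)
  # order is preserved
  expect_true(is.ordered(f))
})

test_that("bonferroni threshold arithmetic", {
  expect_identical(bonferroni_threshold(0.05, 10), 0.005)
  expect_identical(bonferroni_threshold(0.07, 1), 0.07)
  expect_identical(bonferroni_threshold(0.05, 10) * 10, 0.05)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("adjusted and unadjusted ORs agree when covariates are independent", {
  set.seed(67)
  n <- 20000
  z <- rnorm(n)
  cov <- data.frame(image_id = as.character(seq_len(n)),
                    age = rnorm(n, 73, 5), height = rnorm(n, 174, 7),
                    weight = rnorm(n, 84, 13),
                    race = sample(c("white", "asian"), n, TRUE, c(0.9, 0.1)))
  y <- rbinom(n, 1, plogis(-2.5 + log(1.3) * z))
  un <- fit_logistic(y, z)
  ad <- fit_logistic(y, z, covariates = cov, ids = cov$image_id)
  expect_equal(ad$or_per_sd, un$or_per_sd, tolerance = 0.02)
  expect_true(ad$adjusted)
})

test_that("the battery has the configured cardinality and flags planted modes", {
  set.seed(68)
  n <- 4000
  scores <- data.frame(image_id = as.character(seq_len(n)),
                       mode1 = rnorm(n), mode2 = rnorm(n), mode3 = rnorm(n))
  # only mode 2 is causal, log-OR log(1.3)
  y <- rbinom(n, 1, plogis(qlogis(0.08) + log(1.3) * scores$mode2))
  outcomes <- data.frame(image_id = scores$image_id, rhoa_croft2 = y == 1)
  bat <- run_association_battery(scores, outcomes, covariates = NULL,
                                 outcome_names = "rhoa_croft2",
                                 modes = 1:3, adjusted = FALSE)
  expect_equal(nrow(bat), 3L)              # 3 modes x 1 outcome x 1 setting
  thr <- bonferroni_threshold(0.05, 3)
  expect_true(bat$significant[bat$exposure == "mode2"])
  expect_false(any(bat$significant[bat$exposure != "mode2"]))
  expect_true(all(bat$p[bat$exposure == "mode2"] < thr))

  # 10 modes x 1 outcome x 2 adjustment settings -> 20 rows
  scores10 <- cbind(scores[1],
                    as.data.frame(matrix(rnorm(n * 10), n,
                                         dimnames = list(NULL, paste0("mode", 1:10)))))
  cov <- data.frame(image_id = scores$image_id, age = rnorm(n, 73, 5),
                    height = rnorm(n, 174, 7), weight = rnorm(n, 84, 13),
                    race = "white")
  bat2 <- run_association_battery(scores10, outcomes, covariates = cov,
                                  outcome_names = "rhoa_croft2", modes = 1:10)
  expect_equal(nrow(bat2), 20L)
  expect_equal(sum(bat2$adjusted), 10L)
})
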