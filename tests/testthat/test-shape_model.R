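test_that("a one-dimensional shape family yields exactly one mode along it", {
  set.seed(31)
  base <- random_shape(12)
  f <- rnorm(24); f <- f / sqrt(sum(f^2))
  X <- t(sapply(rnorm(40, sd = 2), function(b) base + b * f))
  m <- fit_shape_model(X, k = 1)
  expect_equal(sum(m$all_eigenvalues > 1e-10), 1L)
  expect_gt(abs(sum(m$eigenvectors[1, ] * f)), 0.999)
})

test_that("variance bookkeeping satisfies the trace identity", {
  set.seed(32)
  X <- matrix(rnorm(30 * 16), 30, 16)
  m <- fit_shape_model(X, k = 10)
  expect_equal(sum(m$all_eigenvalues) / m$total_variance, 1, tolerance = 1e-10)
  full <- list(variance_fraction = m$all_eigenvalues / m$total_variance)
  expect_equal(variance_explained(full), 100, tolerance = 1e-8)
  expect_equal(variance_explained(m, integer(0)), 0)
  expect_error(variance_explained(m, 99), "out of range")
})

test_that("model contracts hold: orthonormality, ordering, score normalization", {
  set.seed(33)
  cfg <- default_sim_config(n = 150, seed = 9)
  al <- gpa(sample_shapes(cfg)$landmarks)
  m <- fit_shape_model(al, k = 8)
  G <- m$eigenvectors %*% t(m$eigenvectors)
  expect_equal(G, diag(8), tolerance = 1e-8)
  expect_true(all(diff(m$eigenvalues) <= 1e-12))
  expect_true(all(m$score_norm$sd > 0))
  sc <- score_shapes(m, al)
  expect_equal(unname(colMeans(as.matrix(sc[, -1]))), rep(0, 8), tolerance = 1e-8)
  expect_equal(unname(apply(as.matrix(sc[, -1]), 2, sd)), rep(1, 8), tolerance = 1e-8)
  # eigen-sign convention: largest-|loading| coordinate is positive
  for (j in 1:8) {
    v <- m$eigenvectors[j, ]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("scoring and reconstruction invert each other", {
  set.seed(34)
  # data confined to the achievable rank (2P - 4) so the retained basis is
  # complete for it and the round trip is exact
  k_full <- 16
  Q <- qr.Q(qr(matrix(rnorm(20 * k_full), 20, k_full)))
  X <- matrix(rnorm(40 * k_full, sd = 2), 40, k_full) %*% t(Q)
  X <- sweep(X, 2, rnorm(20), "+")
  m <- fit_shape_model(X, k = k_full)

  # mean shape scores to raw 0 on every mode
  sc0 <- score_shapes(m, matrix(m$mean_shape, 1))
  expect_equal(unname(as.matrix(sc0[, -1])[1, ]),
               unname(-m$score_norm$mean / m$score_norm$sd), tolerance = 1e-8)

  # direct construction: mean + 2 raw-SD along mode 1 scores 2 SD units
  probe <- m$mean_shape + 2 * m$score_norm$sd[1] * m$eigenvectors[1, ] +
    m$score_norm$mean[1] * m$eigenvectors[1, ]
  sc2 <- score_shapes(m, matrix(probe, 1))
  expect_equal(sc2$mode1, 2, tolerance = 1e-8)

  # all-zero scores on a centered model reconstruct the mean
  expect_equal(reconstruct(m, -m$score_norm$mean / m$score_norm$sd),
               unname(m$mean_shape), tolerance = 1e-8)

  # +/-2 SD reconstructions are symmetric about the mean along eigvec 1
  splus <- reconstruct(m, c(2, rep(0, k_full - 1)))
  sminus <- reconstruct(m, c(-2, rep(0, k_full - 1)))
  mid <- (splus + sminus) / 2
  expect_equal(mid, reconstruct(m, rep(0, k_full)), tolerance = 1e-8)

  # full-rank round trip: x -> scores -> x
  sc <- score_shapes(m, X)
  for (i in c(1, 17, 40)) {
    expect_equal(reconstruct(m, unlist(sc[i, -1])), unname(X[i, ]),
                 tolerance = 1e-8)
  }

  expect_error(reconstruct(m, rep(0, k_full + 1)), "expected")
  expect_error(score_shapes(m, matrix(0, 1, 10)), "mismatch")
})

test_that("planted eigenvalue spectrum (9, 4, 1) is recovered at n = 2000", {
  set.seed(35)
  P <- 20
  base <- random_shape(P) * 10
  Q <- qr.Q(qr(matrix(rnorm(2 * P * 3), 2 * P, 3)))
  sds <- sqrt(c(9, 4, 1))
  B <- matrix(rnorm(2000 * 3), 2000, 3) %*% diag(sds)
  X <- matrix(rep(base, each = 2000), 2000) + B %*% t(Q)
  m <- fit_shape_model(X, k = 3)
  expect_lt(max(abs(m$eigenvalues - c(9, 4, 1)) / c(9, 4, 1)), 0.10)
})

test_that("outlier flagging matches the 4 SD review rule", {
  sc <- data.frame(image_id = c("a", "b", "c"),
                   mode1 = c(0.2, 4.1, -1),
                   mode2 = c(-4.5, 0, 0.3))
  fl <- flag_outliers(sc)
  expect_equal(nrow(fl), 2L)
  expect_setequal(fl$image_id, c("a", "b"))
  expect_equal(fl$mode[fl$image_id == "b"], 1L)
  # all scores within the band -> empty
  expect_equal(nrow(flag_outliers(data.frame(image_id = "a", mode1 = 3.9))), 0L)
})

test_that("flag rate for standard-normal scores matches the normal tail", {
  set.seed(36)
  n <- 1e6
  sc <- data.frame(image_id = as.character(seq_len(n)), mode1 = rnorm(n))
  rate <- nrow(flag_outliers(sc)) / n
  p <- 2 * pnorm(-4)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(rate - p), 4 * se)
})

test_that("model JSON serialization round-trips scores", {
  set.seed(37)
  al <- gpa(sample_shapes(default_sim_config(n = 40, seed = 2))$landmarks)
  m <- fit_shape_model(al, k = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_model(m, path, seed = 2)
  m2 <- read_shape_model(path)
  expect_equal(score_shapes(m2, al), score_shapes(m, al), tolerance = 1e-12)
})

test_that("rank guards reject impossible k", {
  set.seed(38)
  X <- matrix(rnorm(20 * 16), 20, 16)
  expect_error(fit_shape_model(X, k = 20), "smaller than the training cohort")
  # similarity alignment removes 4 dof: achievable rank is 2P - 4 = 12
  expect_warning(fit_shape_model(X, k = 15), "capping")
})
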