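# Independent oracles and small fixtures used across test files.

# Brute-force ordinary Procrustes: numeric minimization over
# (scale, rotation, translation), independent of the closed-form path.
brute_force_opa <- function(shape, reference, n_starts = 8L) {
  sxy <- shape_to_xy(shape)
  rxy <- shape_to_xy(reference)
  obj <- function(par) {
    s <- exp(par[1]); th <- par[2]
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    moved <- s * sxy %*% t(R)
    moved[, 1] <- moved[, 1] + par[3]
    moved[, 2] <- moved[, 2] + par[4]
    sum((moved - rxy)^2)
  }
  best <- NULL
  for (th0 in seq(0, 2 * pi, length.out = n_starts + 1L)[-(n_starts + 1L)]) {
    fit <- stats::optim(c(0, th0, 0, 0), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the best start with gradient-based refinement
  for (i in 1:3)
    best <- stats::optim(best$par, obj, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14))
  sqrt(best$value)
}

# Independent Croft aggregation oracle: lookup over feature-presence flags,
# written as a table rather than the package's branch logic.
croft_oracle <- function(osteo, jsn, scler, cysts, deform) {
  nfeat <- osteo + jsn + scler + cysts
  if (nfeat == 0L) return(0L)
  if (nfeat == 1L && osteo) return(1L)
  if (nfeat == 1L && jsn) return(2L)
  if (nfeat == 1L) return(0L)          # sclerosis-only or cysts-only
  if (nfeat == 2L) return(3L)
  if (deform) return(5L)
  4L
}

# a reading row with every grade zero
zero_reading <- function(n = 1L) {
  cols <- c("jsn_medial", "jsn_lateral", "jsn_concentric",
            "osteo_lat_acetabular", "osteo_lat_femoral",
            "osteo_inf_acetabular", "osteo_inf_femoral",
            "cysts", "sclerosis", "head_deformity")
  df <- as.data.frame(matrix(0L, n, length(cols)))
  names(df) <- cols
  df
}

# small random shapes for property tests (Gaussian point clouds are
# nondegenerate with probability 1)
random_shape <- function(P = 10L) stats::rnorm(2L * P, sd = 5)

# apply a similarity transform (s, theta, t) to a 2P vector
apply_similarity <- function(v, s = 1, theta = 0, tx = 0, ty = 0) {
  m <- shape_to_xy(v)
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  m2 <- s * m %*% t(R)
  m2[, 1] <- m2[, 1] + tx
  m2[, 2] <- m2[, 2] + ty
  xy_to_shape(m2)
}

centroid_size <- function(v) {
  m <- shape_to_xy(v)
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

# compare the closed-form residual with the numeric minimizer; near-zero
# residuals are compared on the squared scale because the minimizer's sqrt
# amplifies its convergence error for similar pairs
expect_opa_matches_brute_force <- function(x, y) {
  d_closed <- align_pair(x, y)$distance
  d_brute <- brute_force_opa(x, y)
  expect_lt(abs(d_closed^2 - d_brute^2), 1e-6)
  if (d_brute > 1e-3)
    expect_equal(d_closed, d_brute, tolerance = 1e-6)
}
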