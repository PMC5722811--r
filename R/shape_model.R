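# PCA point-distribution model over Procrustes-aligned coordinates.
#
# Modes are eigenvectors of the covariance matrix of aligned coordinate
# vectors about the Procrustes mean (covariance, not correlation: the
# standard point-distribution-model recipe). An individual's raw score on
# mode j is the projection of (shape - mean) onto eigenvector j; scores are
# reported in SD units after standardising by the training cohort's raw
# projection mean and SD, so training-cohort scores have mean 0 and SD 1
# per mode by construction.

#' Fit a PCA shape model to an aligned cohort
#'
#' Eigen-decomposes the covariance of the aligned coordinate vectors about
#' their mean. Eigenvector signs follow a fixed convention: each eigenvector
#' is oriented so that its largest-absolute loading is positive (ties broken
#' by lowest index), making mode signs reproducible across runs and
#' platforms. Similarity alignment removes 4 degrees of freedom in 2D, so at
#' most `min(n - 1, 2P - 4)` meaningful modes exist.
#'
#' @param aligned an `aligned_shapes` object from [gpa()], or an n x 2P
#'   matrix of aligned coordinates.
#' @param k number of modes to retain for scoring (default 10). The model
#'   additionally records the full eigenvalue spectrum for variance
#'   bookkeeping.
#' @return An object of class `shape_model`: `mean_shape`, `eigenvectors`
#'   (k x 2P, orthonormal rows), `eigenvalues` (length k, non-increasing),
#'   `variance_fraction` (length k, fractions of the FULL trace),
#'   `total_variance`, `score_norm` (data frame of per-mode raw projection
#'   `mean` and `sd` over the training cohort), `n_train`, `P`, `k`.
#' @export
fit_shape_model <- function(aligned, k = 10L) {
  X <- if (inherits(aligned, "aligned_shapes")) aligned$shapes else as.matrix(aligned)
  n <- nrow(X)
  P <- ncol(X) / 2L
  max_rank <- min(n - 1L, 2L * P - 4L)
  if (k >= n) stop("k must be smaller than the training cohort size", call. = FALSE)
  if (k > max_rank) {
    warning(sprintf("k = %d exceeds achievable rank %d; capping", k, max_rank))
    k <- max_rank
  }
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2L, mean_shape)
  covm <- crossprod(Xc) / (n - 1L)
  eig <- eigen(covm, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  total <- sum(vals)
  vecs <- t(eig$vectors[, seq_len(k), drop = FALSE])
  # sign convention: largest-|loading| coordinate positive, first index wins ties
  for (j in seq_len(k)) {
    v <- vecs[j, ]
    imax <- which.max(abs(v))[1]
    if (v[imax] < 0) vecs[j, ] <- -v
  }
  raw <- Xc %*% t(vecs)                      # n x k raw projections
  sn <- data.frame(mean = colMeans(raw),
                   sd = apply(raw, 2L, stats::sd))
  if (any(sn$sd <= 0))
    stop("zero-variance mode among the retained k; reduce k", call. = FALSE)
  structure(list(mean_shape = mean_shape,
                 eigenvectors = vecs,
                 eigenvalues = vals[seq_len(k)],
                 variance_fraction = vals[seq_len(k)] / total,
                 all_eigenvalues = vals,
                 total_variance = total,
                 score_norm = sn,
                 n_train = n, P = P, k = k),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> P = %d, k = %d modes, n_train = %d\n", x$P, x$k, x$n_train))
  cat(sprintf("  variance explained by retained modes: %.1f%%\n",
              100 * sum(x$variance_fraction)))
  invisible(x)
}

#' Score configurations in SD units per mode
#'
#' Projects each aligned shape (minus the model mean) onto the eigenvectors
#' and standardises each mode by the training cohort's raw projection mean
#' and SD, yielding scores in cohort SD units.
#'
#' @param model a [fit_shape_model()] object.
#' @param aligned an `aligned_shapes` object or n x 2P matrix in the model's
#'   frame (see [align_to_reference()] for out-of-sample shapes).
#' @return data frame: `image_id` plus columns `mode1..modek` of SD-unit
#'   scores.
#' @export
score_shapes <- function(model, aligned) {
  X <- if (inherits(aligned, "aligned_shapes")) aligned$shapes else as.matrix(aligned)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != 2L * model$P)
    stop("point count mismatch between shapes and model", call. = FALSE)
  raw <- sweep(X, 2L, model$mean_shape) %*% t(model$eigenvectors)
  z <- sweep(sweep(raw, 2L, model$score_norm$mean), 2L, model$score_norm$sd, "/")
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("img_%d", seq_len(nrow(X)))
  out <- data.frame(image_id = ids, z, stringsAsFactors = FALSE)
  names(out) <- c("image_id", sprintf("mode%d", seq_len(model$k)))
  rownames(out) <- NULL
  out
}

#' Reconstruct a shape at given SD-unit mode scores
#'
#' `mean + sum_j (raw_j) * v_j` where `raw_j` de-standardises the SD score
#' through the model's `score_norm`. With all modes and a shape's own scores
#' the round trip reproduces the aligned shape.
#'
#' @param model a `shape_model`.
#' @param sd_scores numeric vector of length `model$k` (SD units).
#' @return 2P coordinate vector.
#' @export
reconstruct <- function(model, sd_scores) {
  if (length(sd_scores) != model$k)
    stop(sprintf("expected %d scores, got %d", model$k, length(sd_scores)), call. = FALSE)
  raw <- sd_scores * model$score_norm$sd + model$score_norm$mean
  as.numeric(model$mean_shape + as.vector(t(model$eigenvectors) %*% raw))
}

#' Percentage of total shape variance explained by a subset of modes
#'
#' @param model a `shape_model` (or any list with a `variance_fraction`
#'   element).
#' @param mode_subset integer indices within `1..k`; empty subset gives 0.
#' @return percentage (0-100).
#' @export
variance_explained <- function(model, mode_subset = seq_along(model$variance_fraction)) {
  if (length(mode_subset) == 0L) return(0)
  mode_subset <- as.integer(mode_subset)
  if (any(mode_subset < 1L | mode_subset > length(model$variance_fraction)))
    stop("mode index out of range", call. = FALSE)
  100 * sum(model$variance_fraction[mode_subset])
}

#' Flag individuals with extreme mode scores
#'
#' Lists every (image, mode) pair whose absolute SD-unit score exceeds the
#' threshold, mirroring the manual-review workflow in which images scoring
#' beyond +/-4 SD on any mode are checked for point-placement errors.
#' Flagged images are reported, not dropped.
#'
#' @param scores data frame from [score_shapes()].
#' @param threshold SD units (default 4).
#' @return data frame with columns `image_id`, `mode`, `score`; zero rows
#'   when no score exceeds the threshold.
#' @export
flag_outliers <- function(scores, threshold = 4) {
  mode_cols <- grep("^mode[0-9]+$", names(scores), value = TRUE)
  out <- do.call(rbind, lapply(mode_cols, function(mc) {
    hit <- abs(scores[[mc]]) > threshold
    if (!any(hit)) return(NULL)
    data.frame(image_id = scores$image_id[hit],
               mode = as.integer(sub("mode", "", mc)),
               score = scores[[mc]][hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(image_id = character(0), mode = integer(0), score = numeric(0))
  out[order(out$image_id, out$mode), , drop = FALSE]
}

#' Serialize a shape model to JSON
#'
#' @param model a `shape_model`.
#' @param path output path.
#' @param seed optional integer recorded as provenance.
#' @return `path`, invisibly.
#' @export
write_shape_model <- function(model, path, seed = NULL) {
  obj <- list(P = model$P, k = model$k, n_train = model$n_train,
              mean_shape = model$mean_shape,
              eigenvectors = model$eigenvectors,
              eigenvalues = model$eigenvalues,
              variance_fraction = model$variance_fraction,
              total_variance = model$total_variance,
              score_norm = model$score_norm,
              seed = seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a shape model from JSON
#'
#' @param path path written by [write_shape_model()].
#' @return a `shape_model`.
#' @export
read_shape_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean_shape = as.numeric(obj$mean_shape),
                 eigenvectors = matrix(unlist(obj$eigenvectors), nrow = obj$k, byrow = FALSE,
                                       dimnames = NULL),
                 eigenvalues = as.numeric(obj$eigenvalues),
                 variance_fraction = as.numeric(obj$variance_fraction),
                 all_eigenvalues = as.numeric(obj$eigenvalues),
                 total_variance = obj$total_variance,
                 score_norm = as.data.frame(obj$score_norm),
                 n_train = obj$n_train, P = obj$P, k = obj$k),
            class = "shape_model")
}
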