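# Ordinary and generalized Procrustes superimposition in 2D.
#
# The similarity group here is scaling + rotation + translation WITHOUT
# reflection: anatomical chirality must be preserved (left hips are mirrored
# into the right frame upstream, never by the aligner). The 2D closed form is
# computed in the complex plane: with centered configurations z (shape) and w
# (reference) as complex P-vectors, the optimal scale*rotation is
# conj(z)'w / conj(z)'z, which never contains a reflection.

complexify <- function(v) {
  m <- shape_to_xy(v)
  complex(real = m[, 1], imaginary = m[, 2])
}

check_nondegenerate <- function(v, what = "shape") {
  cs <- centroid_size(v)
  if (!is.finite(cs) || cs <= .Machine$double.eps * length(v))
    stop(sprintf("degenerate %s: zero centroid size (all points coincident)", what),
         call. = FALSE)
  cs
}

#' Align one configuration to a reference (ordinary Procrustes)
#'
#' Finds the similarity transform (scale, rotation, translation; no
#' reflection) minimizing the sum of squared point distances to the
#' reference, by the closed-form 2D solution.
#'
#' @param shape numeric 2P vector.
#' @param reference numeric 2P vector with the same P.
#' @return A list with `aligned` (2P vector), `transform` (list with `scale`,
#'   `rotation` in radians in (-pi, pi], `translation` length-2), and
#'   `distance` (root sum of squared residuals).
#' @export
align_pair <- function(shape, reference) {
  if (length(shape) != length(reference))
    stop("shape and reference must have equal point counts", call. = FALSE)
  check_nondegenerate(shape)
  check_nondegenerate(reference, "reference")
  cs <- centroid_xy(shape)
  cr <- centroid_xy(reference)
  z <- complexify(shape) - complex(real = cs[1], imaginary = cs[2])
  w <- complexify(reference) - complex(real = cr[1], imaginary = cr[2])
  a <- sum(Conj(z) * w) / sum(Conj(z) * z)     # scale * exp(i rotation)
  zal <- a * z + complex(real = cr[1], imaginary = cr[2])
  aligned <- c(Re(zal), Im(zal))
  # translation maps the original (uncentered) shape: t = cr - a * cs
  tr <- complex(real = cr[1], imaginary = cr[2]) -
    a * complex(real = cs[1], imaginary = cs[2])
  list(
    aligned = aligned,
    transform = list(scale = Mod(a), rotation = Arg(a),
                     translation = c(Re(tr), Im(tr))),
    distance = sqrt(sum(Mod(a * z - w)^2))
  )
}

#' Procrustes distance between two configurations
#'
#' Root sum of squared point differences after optimal similarity
#' superimposition of `a` onto `b`. With full similarity alignment
#' (including scale) the value is symmetric in its arguments up to the
#' normalisation of centroid size; both inputs are standardised to unit
#' centroid size first so the metric is symmetric.
#'
#' @param a,b numeric 2P vectors.
#' @return Nonnegative scalar; 0 iff `a` and `b` differ by a similarity
#'   transform.
#' @export
procrustes_distance <- function(a, b) {
  check_nondegenerate(a); check_nondegenerate(b)
  std <- function(v) {
    ct <- centroid_xy(v)
    v0 <- v - rep(ct, each = length(v) / 2L)
    v0 / centroid_size(v)
  }
  align_pair(std(a), std(b))$distance
}

#' Generalized Procrustes alignment of a cohort
#'
#' Iterative scheme: align every configuration to the current mean, recompute
#' the mean, re-standardise the mean to centroid at the origin and unit
#' centroid size, and repeat until the root-mean-square change of the mean
#' falls below `tol` or `max_iter` is reached. The initial reference is the
#' first configuration, centered and scaled to unit centroid size.
#'
#' @param lms a [landmark_set()] or an n x 2P coordinate matrix, n >= 2.
#' @param tol convergence tolerance on the RMS change of the mean shape.
#' @param max_iter maximum number of iterations.
#' @return An object of class `aligned_shapes`: list with `shapes` (n x 2P
#'   aligned matrix), `mean_shape` (2P, centroid at origin, unit centroid
#'   size), `transforms`, `iterations`, `converged`, `objective` (per
#'   iteration: sum of squared distances of aligned shapes to their mean,
#'   non-increasing), `ids`.
#' @export
gpa <- function(lms, tol = 1e-8, max_iter = 100L) {
  if (inherits(lms, "landmark_set")) {
    X <- lms$coords; ids <- lms$ids
  } else {
    X <- as.matrix(lms); ids <- rownames(X)
  }
  n <- nrow(X)
  if (n < 2L) stop("generalized Procrustes needs at least 2 shapes", call. = FALSE)
  for (i in seq_len(n)) check_nondegenerate(X[i, ])
  std <- function(v) {
    ct <- centroid_xy(v)
    v0 <- v - rep(ct, each = length(v) / 2L)
    v0 / centroid_size(v0)
  }
  ref <- std(X[1, ])
  aligned <- X
  converged <- FALSE
  iter <- 0L
  transforms <- vector("list", n)
  objective <- numeric(0)
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      fit <- align_pair(X[i, ], ref)
      aligned[i, ] <- fit$aligned
      transforms[[i]] <- fit$transform
    }
    m <- colMeans(aligned)
    # gauge-fixed: measured relative to a unit-centroid-size mean so the
    # mean renormalization step cannot inflate the recorded objective
    objective <- c(objective, sum(sweep(aligned, 2L, m)^2) / centroid_size(m)^2)
    new_ref <- std(m)
    delta <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol) { converged <- TRUE; break }
  }
  # final pass so every shape is optimally aligned to the converged mean
  for (i in seq_len(n)) {
    fit <- align_pair(X[i, ], ref)
    aligned[i, ] <- fit$aligned
    transforms[[i]] <- fit$transform
  }
  rownames(aligned) <- ids
  structure(list(shapes = aligned, mean_shape = ref, transforms = transforms,
                 iterations = iter, converged = converged,
                 objective = objective, ids = ids),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> n = %d, P = %d, %d iteration(s), converged: %s\n",
              nrow(x$shapes), ncol(x$shapes) / 2L, x$iterations, x$converged))
  invisible(x)
}

#' Align new configurations into a fitted model frame
#'
#' Ordinary Procrustes alignment of each configuration onto a fixed
#' reference (typically a model's `mean_shape`), without re-estimating the
#' mean. Used to score shapes that were not in the training cohort.
#'
#' @param lms a [landmark_set()] or n x 2P matrix.
#' @param reference 2P vector.
#' @return n x 2P matrix of aligned coordinates.
#' @export
align_to_reference <- function(lms, reference) {
  X <- if (inherits(lms, "landmark_set")) lms$coords else as.matrix(lms)
  out <- t(apply(X, 1L, function(v) align_pair(v, reference)$aligned))
  rownames(out) <- rownames(X)
  out
}
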