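# Landmark data model and file I/O.
#
# Coordinate convention: image pixel frame, origin top-left, y increasing
# downward (the raster convention of DXA landmark tools).  A configuration of
# P points is stored as a 2P vector stacked c(x_1..x_P, y_1..y_P); a cohort is
# an n x 2P matrix with image ids as rownames.

#' Construct a set of landmark configurations
#'
#' A `landmark_set` holds one or more hip landmark configurations sharing a
#' common point count `P`. Each configuration is an ordered sequence of
#' (x, y) pixel coordinates following the anatomical ordering of the
#' template; coordinates are stored row-wise as `c(x_1..x_P, y_1..y_P)`.
#'
#' @param coords numeric matrix, n x 2P, one configuration per row
#'   (columns `x1..xP` then `y1..yP`), or a single 2P vector.
#' @param ids character vector of image ids (defaults to rownames or `img_i`).
#' @param side character vector, `"left"` or `"right"` per configuration.
#' @return An object of class `landmark_set` with elements `coords`, `ids`,
#'   `side` and `P`.
#' @export
landmark_set <- function(coords, ids = NULL, side = "right") {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 1)
  coords <- as.matrix(coords)
  if (ncol(coords) %% 2L != 0L)
    stop("coords must have an even number of columns (2P)", call. = FALSE)
  P <- ncol(coords) / 2L
  n <- nrow(coords)
  if (is.null(ids)) ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("img_%d", seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("length(ids) must equal nrow(coords)", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicated image ids", call. = FALSE)
  side <- rep_len(as.character(side), n)
  if (!all(side %in% c("left", "right")))
    stop("side must be 'left' or 'right'", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in landmark set", call. = FALSE)
  rownames(coords) <- ids
  colnames(coords) <- c(sprintf("x%d", seq_len(P)), sprintf("y%d", seq_len(P)))
  structure(list(coords = coords, ids = ids, side = side, P = P),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d configuration(s), P = %d points\n",
              length(x$ids), x$P))
  invisible(x)
}

#' @export
length.landmark_set <- function(x) length(x$ids)

#' Reshape a stacked 2P coordinate vector to a P x 2 matrix
#'
#' @param v numeric 2P vector `c(x_1..x_P, y_1..y_P)`.
#' @return P x 2 matrix with columns `x`, `y`.
#' @export
shape_to_xy <- function(v) {
  P <- length(v) / 2L
  matrix(v, ncol = 2L, dimnames = list(NULL, c("x", "y")))
}

#' Flatten a P x 2 coordinate matrix to a stacked 2P vector
#'
#' @param m P x 2 matrix of (x, y) coordinates.
#' @return numeric 2P vector `c(x_1..x_P, y_1..y_P)`.
#' @export
xy_to_shape <- function(m) as.numeric(m)

centroid_xy <- function(v) {
  m <- shape_to_xy(v)
  colMeans(m)
}

# Centroid size: root sum of squared distances of points to their centroid.
centroid_size <- function(v) {
  m <- shape_to_xy(v)
  sqrt(sum(sweep(m, 2, colMeans(m))^2))
}

#' Read landmark configurations from a long-format CSV
#'
#' Expects a header `image_id,point_index,x,y` with optional `side`;
#' `point_index` is 0-based and must cover `0..P-1` exactly once per image.
#' Images with missing or duplicated indices are rejected with an error
#' naming the image and offending index.
#'
#' @param path CSV file path.
#' @param template optional [make_hip_template()] object; when supplied the
#'   file's point count must match `template$P`.
#' @param P expected point count when no template is given (default 58).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, template = NULL, P = if (!is.null(template)) template$P else 58L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "point_index", "x", "y")
  if (!all(req %in% names(df)))
    stop("landmark file must have columns image_id, point_index, x, y", call. = FALSE)
  if (nrow(df) == 0L)
    return(landmark_set(matrix(numeric(0), 0, 2L * P)))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("non-numeric coordinate in landmark file", call. = FALSE)
  ids <- unique(df$image_id)
  full <- 0:(P - 1L)
  coords <- matrix(NA_real_, length(ids), 2L * P)
  side <- character(length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$image_id == ids[i], , drop = FALSE]
    idx <- sub$point_index
    if (anyDuplicated(idx))
      stop(sprintf("image '%s': duplicated point_index %s", ids[i],
                   idx[duplicated(idx)][1]), call. = FALSE)
    missing_idx <- setdiff(full, idx)
    if (length(missing_idx) || length(idx) != P)
      stop(sprintf("image '%s': missing point_index %s", ids[i],
                   if (length(missing_idx)) missing_idx[1] else "(extra indices present)"),
           call. = FALSE)
    ord <- order(idx)
    coords[i, ] <- c(sub$x[ord], sub$y[ord])
    side[i] <- if ("side" %in% names(sub)) as.character(sub$side[1]) else "right"
  }
  landmark_set(coords, ids = as.character(ids), side = side)
}

#' Write landmark configurations to a long-format CSV
#'
#' Inverse of [read_landmarks()]: coordinates survive the round trip
#' bit-exactly (written with full precision).
#'
#' @param lms a [landmark_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lms, path) {
  stopifnot(inherits(lms, "landmark_set"))
  P <- lms$P
  n <- length(lms$ids)
  if (n == 0L) {
    writeLines("image_id,point_index,x,y,side", path)
    return(invisible(path))
  }
  df <- data.frame(
    image_id = rep(lms$ids, each = P),
    point_index = rep(0:(P - 1L), times = n),
    x = as.vector(t(lms$coords[, seq_len(P), drop = FALSE])),
    y = as.vector(t(lms$coords[, P + seq_len(P), drop = FALSE])),
    side = rep(lms$side, each = P),
    stringsAsFactors = FALSE
  )
  # format at full double precision so read/write is the identity
  df$x <- formatC(df$x, format = "g", digits = 17)
  df$y <- formatC(df$y, format = "g", digits = 17)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mirror a left-hip configuration into the right-hip frame
#'
#' Reflects x-coordinates about a vertical axis `x = axis_x` and relabels the
#' side as right. Template indices are anatomical labels (point i is the same
#' anatomical locus on either side), so mirroring preserves point order; no
#' re-indexing is needed. Applying the function twice (with the side label
#' reset) restores the original coordinates.
#'
#' @param lms a [landmark_set()] (all sides must be `"left"`; right-side
#'   configurations pass through unchanged with a warning).
#' @param axis_x x position in pixels of the mirror axis.
#' @return A [landmark_set()] with all sides `"right"`.
#' @export
mirror_to_right <- function(lms, axis_x = 0) {
  stopifnot(inherits(lms, "landmark_set"))
  is_left <- lms$side == "left"
  if (any(!is_left))
    warning("configurations already right-sided were left unchanged")
  coords <- lms$coords
  P <- lms$P
  if (any(is_left)) {
    xs <- coords[is_left, seq_len(P), drop = FALSE]
    coords[is_left, seq_len(P)] <- 2 * axis_x - xs
  }
  landmark_set(coords, ids = lms$ids, side = "right")
}
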