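# Inter-operator landmark placement accuracy.
#
# For each (image, point), the consensus position is the average over ALL
# operators including the one being scored; an operator's accuracy is the
# median Euclidean distance to that consensus, pooled over every (image,
# point) pair (not a median of per-image medians). A median of <= 3 pixels
# denotes acceptable placement accuracy.

#' Median point-to-point placement accuracy of one operator
#'
#' @param placements data frame with columns `image_id`, `operator`,
#'   `point_index`, `x`, `y`: one row per operator per point per image. Every
#'   operator must have placed every point on every image, and each image
#'   needs at least 2 operators.
#' @param operator operator id to score.
#' @return median distance in pixels over all (image, point) pairs.
#' @export
point_to_point_accuracy <- function(placements, operator) {
  d <- operator_distances(placements)
  sel <- d$operator == operator
  if (!any(sel)) stop("operator not present in placements: ", operator, call. = FALSE)
  stats::median(d$distance[sel])
}

# distances of every operator's every point to the all-operator average
operator_distances <- function(placements) {
  req <- c("image_id", "operator", "point_index", "x", "y")
  if (!all(req %in% names(placements)))
    stop("placements need columns image_id, operator, point_index, x, y", call. = FALSE)
  n_ops <- tapply(placements$operator, placements$image_id,
                  function(o) length(unique(o)))
  if (any(n_ops < 2L))
    stop("every image needs placements from at least 2 operators", call. = FALSE)
  key <- interaction(placements$image_id, placements$point_index, drop = TRUE)
  mx <- tapply(placements$x, key, mean)
  my <- tapply(placements$y, key, mean)
  k <- as.character(key)
  data.frame(
    image_id = placements$image_id,
    operator = placements$operator,
    point_index = placements$point_index,
    distance = sqrt((placements$x - mx[k])^2 + (placements$y - my[k])^2),
    stringsAsFactors = FALSE
  )
}

#' Per-operator placement accuracy report
#'
#' One row per operator with the pooled median point-to-point distance and a
#' pass flag (`median <= threshold`).
#'
#' @param placements as in [point_to_point_accuracy()].
#' @param threshold acceptance threshold in pixels (default 3).
#' @return data frame with columns `operator`, `median_distance`, `pass`.
#' @export
qc_report <- function(placements, threshold = 3) {
  d <- operator_distances(placements)
  ops <- sort(unique(d$operator))
  med <- vapply(ops, function(o) stats::median(d$distance[d$operator == o]),
                numeric(1))
  data.frame(operator = ops, median_distance = unname(med),
             pass = unname(med) <= threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}
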