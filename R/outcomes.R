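# Radiographic and pain outcome construction.
#
# A radiograph reading carries component grades: joint space narrowing (JSN)
# 0-4 at medial, lateral and concentric regions; osteophytes 0-3 at four
# sites (lateral/inferior x acetabular/femoral); cysts, subchondral
# sclerosis and femoral head deformity 0-3; plus a chondrocalcinosis flag.
# The Croft grade aggregates feature presence (any site/region at grade >= 1):
#   0 = no features
#   1 = osteophytosis only
#   2 = JSN only
#   3 = two of {osteophytosis, JSN, sclerosis, cysts}
#   4 = three of those four
#   5 = grade-4 criteria plus femoral head deformity
# Radiographic hip OA (RHOA) is Croft >= 2 (moderate; primary definition) or
# Croft >= 3 (severe; sensitivity definition).

JSN_COLS <- c("jsn_medial", "jsn_lateral", "jsn_concentric")
OSTEO_COLS <- c("osteo_lat_acetabular", "osteo_lat_femoral",
                "osteo_inf_acetabular", "osteo_inf_femoral")

GRADE_RANGES <- c(
  jsn_medial = 4, jsn_lateral = 4, jsn_concentric = 4,
  osteo_lat_acetabular = 3, osteo_lat_femoral = 3,
  osteo_inf_acetabular = 3, osteo_inf_femoral = 3,
  cysts = 3, sclerosis = 3, head_deformity = 3
)

validate_readings <- function(readings) {
  miss <- setdiff(names(GRADE_RANGES), names(readings))
  if (length(miss))
    stop("readings missing grade columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in names(GRADE_RANGES)) {
    g <- readings[[col]]
    if (any(!is.finite(g)) || any(g != round(g)) ||
        any(g < 0) || any(g > GRADE_RANGES[[col]]))
      stop(sprintf("column '%s': grades must be integers in 0..%d",
                   col, GRADE_RANGES[[col]]), call. = FALSE)
  }
  invisible(readings)
}

#' Croft grade (0-5) from component radiograph grades
#'
#' Feature presence means any relevant site/region at grade >= 1. The
#' aggregation is: 0 no features; 1 osteophytosis only; 2 JSN only; 3 two of
#' \{osteophytosis, JSN, sclerosis, cysts\}; 4 three of those four; 5 the
#' grade-4 criteria plus femoral head deformity. The mapping is monotone
#' nondecreasing in every component grade.
#'
#' @param readings data frame with one row per image and columns
#'   `jsn_medial`, `jsn_lateral`, `jsn_concentric` (0-4),
#'   `osteo_lat_acetabular`, `osteo_lat_femoral`, `osteo_inf_acetabular`,
#'   `osteo_inf_femoral`, `cysts`, `sclerosis`, `head_deformity` (0-3).
#' @return integer vector of Croft grades, one per row.
#' @export
croft_grade <- function(readings) {
  validate_readings(readings)
  osteo <- apply(readings[OSTEO_COLS] >= 1, 1L, any)
  jsn <- apply(readings[JSN_COLS] >= 1, 1L, any)
  scler <- readings$sclerosis >= 1
  cysts <- readings$cysts >= 1
  deform <- readings$head_deformity >= 1
  nfeat <- osteo + jsn + scler + cysts
  grade <- integer(nrow(readings))
  grade[osteo & nfeat == 1L] <- 1L
  grade[jsn & nfeat == 1L] <- 2L
  grade[nfeat == 2L] <- 3L
  grade[nfeat >= 3L] <- 4L
  grade[nfeat >= 3L & deform] <- 5L
  grade
}

#' Binary radiographic hip OA case status
#'
#' `croft_grade(readings) >= threshold`; threshold 2 is the primary
#' (moderate) definition, threshold 3 the severe sensitivity definition.
#' Because the definitions are nested, every threshold-3 case is also a
#' threshold-2 case.
#'
#' @param readings as in [croft_grade()].
#' @param threshold Croft grade cut-off (default 2).
#' @return logical vector.
#' @export
rhoa_case <- function(readings, threshold = 2) {
  croft_grade(readings) >= threshold
}

#' Binary presence of a named radiographic feature
#'
#' @param readings as in [croft_grade()].
#' @param feature a grade column name, e.g. `"osteo_lat_acetabular"` or
#'   `"jsn_medial"`, or the pooled groups `"any_osteophyte"` / `"any_jsn"`.
#' @param min_grade cut-off: 1 mild (primary), 2 moderate, 3 severe.
#' @return logical vector.
#' @export
binary_feature <- function(readings, feature, min_grade = 1) {
  validate_readings(readings)
  if (!min_grade %in% 1:3) stop("min_grade must be 1, 2 or 3", call. = FALSE)
  if (feature == "any_osteophyte")
    return(apply(readings[OSTEO_COLS] >= min_grade, 1L, any))
  if (feature == "any_jsn")
    return(apply(readings[JSN_COLS] >= min_grade, 1L, any))
  if (!feature %in% names(GRADE_RANGES))
    stop("unknown feature: ", feature, call. = FALSE)
  readings[[feature]] >= min_grade
}

#' Prevalence as a printed percentage
#'
#' `100 * case_count / n`, rounded half-up to 1 decimal place (the rounding
#' used for printed prevalence tables; base `round()` rounds half to even,
#' which differs on exact halves).
#'
#' @param case_count number of cases (0..n).
#' @param n denominator (> 0).
#' @return percentage with 1 decimal place.
#' @export
prevalence <- function(case_count, n) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (case_count < 0 || case_count > n)
    stop("case_count must be in 0..n", call. = FALSE)
  round_half_up(100 * case_count / n, 1L)
}

#' Round half away from zero
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Construct pain outcomes from raw fields
#'
#' Walking pain (0-4) is dichotomised at >= 1; pain on internal rotation is
#' already binary; WOMAC is the 0-20 composite (pain, stiffness, function).
#'
#' @param pain data frame with columns `pain_internal_rotation` (0/1),
#'   `walking_pain_raw` (0-4), `womac` (0-20); NAs allowed (complete-case
#'   handling happens in the association models).
#' @return the input with a `walking_pain` logical column added.
#' @export
pain_outcomes <- function(pain) {
  stopifnot(all(c("pain_internal_rotation", "walking_pain_raw", "womac") %in% names(pain)))
  ok <- function(v, lo, hi) all(is.na(v) | (v >= lo & v <= hi & v == round(v)))
  if (!ok(pain$walking_pain_raw, 0, 4)) stop("walking_pain_raw must be 0-4", call. = FALSE)
  if (!ok(pain$womac, 0, 20)) stop("womac must be 0-20", call. = FALSE)
  if (!ok(pain$pain_internal_rotation, 0, 1))
    stop("pain_internal_rotation must be 0/1", call. = FALSE)
  pain$walking_pain <- pain$walking_pain_raw >= 1
  pain
}

#' Build the full outcome table used by the association battery
#'
#' Joins radiographic and pain outcomes into one table keyed by `image_id`:
#' RHOA at both Croft thresholds, each osteophyte site at grades >= 1 and
#' >= 2, each JSN region and sclerosis at grade >= 1, the binary pains and
#' the WOMAC composite.
#'
#' @param readings data frame with `image_id` plus grade columns.
#' @param pain data frame with `image_id` plus raw pain fields.
#' @return data frame of derived outcomes, one row per image.
#' @export
build_outcome_table <- function(readings, pain) {
  stopifnot("image_id" %in% names(readings), "image_id" %in% names(pain))
  out <- data.frame(image_id = readings$image_id, stringsAsFactors = FALSE)
  out$croft <- croft_grade(readings)
  out$rhoa_croft2 <- out$croft >= 2
  out$rhoa_croft3 <- out$croft >= 3
  for (col in OSTEO_COLS) {
    out[[paste0(col, "_g1")]] <- binary_feature(readings, col, 1)
    out[[paste0(col, "_g2")]] <- binary_feature(readings, col, 2)
  }
  for (col in JSN_COLS)
    out[[paste0(col, "_g1")]] <- binary_feature(readings, col, 1)
  out$sclerosis_g1 <- binary_feature(readings, "sclerosis", 1)
  pain <- pain_outcomes(pain)
  merge(out, pain[c("image_id", "pain_internal_rotation", "walking_pain", "womac")],
        by = "image_id", all.x = TRUE, sort = FALSE)
}
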