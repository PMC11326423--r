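# Arithmetic of the IHI visual-rating protocol.
#
# Four ordinal criteria are retained: C1 (verticality/roundness of the
# hippocampal body), C2 (verticality and depth of the collateral sulcus),
# C3 (medial position of the hippocampus) and C5 (sulci of the fusiform
# gyrus exceeding the subiculum level). C4 (subiculum bulging) is excluded
# from the protocol: it is nearly constant in the population and unreliable
# to rate, so it is not representable here. Criteria are rated on a 0-2
# scale, in steps of 0.5 for C1-C3 and steps of 1 for C5; the composite
# score is their sum (range 0-8) and a hemisphere is classified as showing
# incomplete hippocampal inversion when the composite is >= 4.

#' IHI criterion identifiers
#'
#' The four ordinal criteria of the incomplete-hippocampal-inversion rating
#' protocol used throughout the package. The historical criterion C4
#' (subiculum bulging) is excluded from the protocol and cannot be used.
#'
#' @return Character vector `c("C1", "C2", "C3", "C5")`.
#' @export
ihi_criteria <- function() c("C1", "C2", "C3", "C5")

#' Composite-score threshold for IHI classification
#' @return The scalar 4: hemispheres with composite score >= 4 are IHI.
#' @export
ihi_threshold <- function() 4

check_criterion <- function(criterion) {
  if (length(criterion) != 1L || !criterion %in% ihi_criteria()) {
    stop_input("`criterion` must be one of ", paste(ihi_criteria(), collapse = ", "),
               " (C4 is excluded from the rating protocol)")
  }
  criterion
}

#' Rating grid of an IHI criterion
#'
#' @param criterion One of `"C1"`, `"C2"`, `"C3"`, `"C5"`.
#' @return Numeric vector of admissible scores: `seq(0, 2, by = 0.5)` for
#'   C1-C3, `0:2` for C5.
#' @export
criterion_grid <- function(criterion) {
  check_criterion(criterion)
  if (criterion == "C5") seq(0, 2, by = 1) else seq(0, 2, by = 0.5)
}

criterion_step <- function(criterion) if (check_criterion(criterion) == "C5") 1 else 0.5

#' Round a continuous prediction onto a criterion's rating grid
#'
#' Regression output is continuous; manual ratings live on a discrete grid.
#' Predictions are rounded to the nearest grid mark (0.5 marks for C1-C3,
#' whole marks for C5) and clamped to the 0-2 rating range. Exact midpoints
#' round up, i.e. toward the more atypical anatomy, so borderline cases are
#' flagged rather than missed.
#'
#' @param raw Numeric vector of finite raw predictions.
#' @param criterion One of `"C1"`, `"C2"`, `"C3"`, `"C5"`.
#' @return Numeric vector on the criterion grid, same length as `raw`.
#' @examples
#' round_prediction(c(0.63, 0.25, 2.4), "C1") # 0.5 0.5 2.0
#' round_prediction(1.7, "C5")                # 2
#' @export
round_prediction <- function(raw, criterion) {
  check_criterion(criterion)
  if (!is.numeric(raw) || any(!is.finite(raw))) {
    stop_input("`raw` must be finite numeric (got non-finite prediction)")
  }
  step <- criterion_step(criterion)
  out <- floor(raw / step + 0.5) * step
  pmin(pmax(out, 0), 2)
}

check_scores <- function(scores) {
  if (is.list(scores)) scores <- unlist(scores)
  if (is.null(names(scores)) || !all(ihi_criteria() %in% names(scores))) {
    missing <- setdiff(ihi_criteria(), names(scores))
    stop_input("incomplete record: missing criterion score(s) ",
               paste(missing, collapse = ", "))
  }
  scores <- scores[ihi_criteria()]
  for (cr in ihi_criteria()) {
    if (!isTRUE(scores[[cr]] %in% criterion_grid(cr))) {
      stop_input("score ", scores[[cr]], " for ", cr, " is not on its rating grid")
    }
  }
  scores
}

#' Composite IHI score
#'
#' Sum of the four criterion scores. Inputs must be on their rating grids
#' (round continuous predictions with [round_prediction()] first); the
#' composite therefore lies on the 0.5 grid in `[0, 8]`.
#'
#' @param scores Named numeric vector (or list) with one entry per criterion
#'   `C1`, `C2`, `C3`, `C5`, each on its grid.
#' @return The composite score, a scalar in `[0, 8]`.
#' @examples
#' composite_score(c(C1 = 1.5, C2 = 1.0, C3 = 0.5, C5 = 1)) # 4
#' @export
composite_score <- function(scores) {
  scores <- check_scores(scores)
  sum(as.numeric(scores))
}

#' Classify a hemisphere as IHI from its composite score
#'
#' @param composite Numeric vector of composite scores in `[0, 8]`.
#' @return Logical vector: `TRUE` where the inversion is incomplete
#'   (composite >= 4).
#' @export
classify_ihi <- function(composite) {
  if (!is.numeric(composite) || any(!is.finite(composite)) ||
      any(composite < 0 | composite > 8)) {
    stop_input("`composite` must lie in [0, 8]")
  }
  composite >= ihi_threshold()
}

# ---- rating-table I/O (TSV dialect) ----------------------------------------

RATING_COLUMNS <- c("subject_id", "hemisphere", "c1", "c2", "c3", "c5",
                    "composite", "ihi_flag", "rater_id", "age", "sex",
                    "weight", "height", "handedness", "centre", "cohort")

#' Read a rating table
#'
#' Rating tables are tab-separated files with one row per subject x
#' hemisphere: columns `subject_id, hemisphere, c1, c2, c3, c5, composite,
#' ihi_flag, rater_id, age, sex, weight, height, handedness, centre, cohort`.
#'
#' @param path Path to a TSV rating table.
#' @return A `data.frame` with the columns above.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_input("rating table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "hemisphere", "c1", "c2", "c3", "c5"), names(df))
  if (length(missing)) {
    stop_input("rating table ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a rating table
#'
#' @param ratings A rating `data.frame` (see [read_ratings()] for the dialect).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Recompute composite/ihi_flag columns from the per-criterion columns.
refresh_composites <- function(df) {
  df$composite <- df$c1 + df$c2 + df$c3 + df$c5
  df$ihi_flag <- classify_ihi(df$composite)
  df
}
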