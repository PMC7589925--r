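TEMPORAL_CLASSES <- c("descending", "ascending", "peak_15", "peak_25",
                      "peak_35", "other")

#' Classify a five-point developmental expression profile
#'
#' Assigns one of six temporal classes to a profile of mean abundances
#' ordered by developmental time-point (5, 15, 25, 35, 45 DPA):
#'
#' * `descending` - monotone non-increasing with at least `fold_min`-fold
#'   end-to-end decrease;
#' * `ascending`  - the mirror pattern;
#' * `peak_15` / `peak_25` / `peak_35` - unique maximum at an interior
#'   time-point;
#' * `other` - anything else (flat profiles included).
#'
#' The classification is scale-invariant: multiplying a profile by a
#' positive constant never changes the class.
#'
#' @param x Numeric vector of length 5, finite and non-negative.
#' @param fold_min Required end-to-end fold change for a monotone trend
#'   to count as descending/ascending (default 2).
#' @return A single class label (character).
#' @export
classify_temporal_pattern <- function(x, fold_min = 2) {
  if (length(x) != 5L) stop("profile must have exactly 5 time-points")
  if (!all(is.finite(x)) || any(x < 0)) {
    stop("profile values must be finite and non-negative")
  }
  d <- diff(x)
  non_inc <- all(d <= 0)
  non_dec <- all(d >= 0)
  if (non_inc && !non_dec && x[1L] > 0 && x[1L] >= fold_min * x[5L]) {
    return("descending")
  }
  if (non_dec && !non_inc && x[5L] > 0 && x[5L] >= fold_min * x[1L]) {
    return("ascending")
  }
  at_max <- which(x == max(x))
  if (length(at_max) == 1L && at_max >= 2L && at_max <= 4L) {
    return(c("peak_15", "peak_25", "peak_35")[at_max - 1L])
  }
  "other"
}

#' Classify every row of a profile matrix
#'
#' @param profiles Numeric matrix with 5 columns (time-points in DPA
#'   order) and feature rownames.
#' @param fold_min Passed to [classify_temporal_pattern()].
#' @return Data frame with `feature_id` and `class`.
#' @export
classify_temporal_patterns <- function(profiles, fold_min = 2) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 5L) stop("profile matrix must have 5 columns")
  cls <- apply(profiles, 1L, classify_temporal_pattern, fold_min = fold_min)
  data.frame(feature_id = rownames(profiles), class = unname(cls),
             stringsAsFactors = FALSE)
}
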