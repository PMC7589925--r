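#' Expression presence of features across library groups
#'
#' A feature is "present" in a group when its maximum (normalized)
#' abundance over the group's libraries exceeds `threshold`. The
#' resulting logical membership matrix supports Venn-style bookkeeping of
#' features exclusive to, or shared among, treatments or time-points.
#'
#' @param x An [abundance_matrix] or numeric matrix (normalized values
#'   recommended).
#' @param group Factor over columns defining the groups (e.g. treatment);
#'   columns with `NA` are ignored.
#' @param threshold Detection floor; a feature is present when its group
#'   maximum is strictly greater than this (default 0).
#' @return Logical matrix, features x groups.
#' @export
expression_membership <- function(x, group, threshold = 0) {
  values <- as_values(x)
  group <- as.factor(group)
  if (length(group) != ncol(values)) {
    stop("`group` must have one entry per library (column)")
  }
  keep <- !is.na(group)
  values <- values[, keep, drop = FALSE]
  group <- droplevels(group[keep])
  out <- vapply(levels(group), function(g) {
    apply(values[, group == g, drop = FALSE], 1L, max) > threshold
  }, logical(nrow(values)))
  rownames(out) <- rownames(values)
  out
}

#' Count features in each Venn region of a membership matrix
#'
#' @param membership Logical matrix as returned by
#'   [expression_membership()].
#' @return Named integer vector; names are `&`-joined group labels
#'   (e.g. `"CG&WS"`), plus `"none"` for features absent everywhere.
#' @export
venn_counts <- function(membership) {
  membership <- as.matrix(membership)
  labs <- apply(membership, 1L, function(row) {
    if (!any(row)) "none" else paste(colnames(membership)[row], collapse = "&")
  })
  tab <- table(labs)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
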