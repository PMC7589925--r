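#' Abundance matrix with library metadata
#'
#' A light container pairing a features-by-libraries numeric matrix with
#' the design coordinates of each library and the unit of measurement,
#' in the spirit of `edgeR::DGEList`.
#'
#' @param values Numeric matrix, features in rows (rownames required),
#'   libraries in columns. No negative entries.
#' @param meta Data frame of library metadata with at least a
#'   `library_id` column matching `colnames(values)` in order. Typical
#'   columns: `genotype` (TG/SG), `treatment` (CG/WS/HS/WH),
#'   `timepoint_dpa` (5-45), `replicate`.
#' @param unit One of `"raw_count"`, `"RPM"`, `"FPKM"`.
#' @param feature_lengths Optional named numeric vector of feature lengths
#'   in nucleotides (required later for FPKM normalization).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, meta, unit = c("raw_count", "RPM", "FPKM"),
                             feature_lengths = NULL) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("`values` must have feature rownames")
  if (any(values < 0)) stop("abundance values must be non-negative")
  meta <- as.data.frame(meta)
  if (!"library_id" %in% names(meta)) stop("`meta` must have a library_id column")
  if (is.null(colnames(values))) colnames(values) <- meta$library_id
  if (!identical(as.character(meta$library_id), colnames(values))) {
    stop("column order of `values` must match meta$library_id")
  }
  if (!is.null(feature_lengths)) {
    if (is.null(names(feature_lengths))) {
      if (length(feature_lengths) != nrow(values)) {
        stop("unnamed `feature_lengths` must match nrow(values)")
      }
      names(feature_lengths) <- rownames(values)
    }
    if (any(feature_lengths[rownames(values)] <= 0, na.rm = TRUE)) {
      stop("feature lengths must be positive")
    }
  }
  structure(
    list(values = values, meta = meta, unit = unit,
         feature_lengths = feature_lengths),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d features x %d libraries [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

as_values <- function(x) {
  if (inherits(x, "abundance_matrix")) x$values else as.matrix(x)
}

#' Reads-per-million normalization
#'
#' Scales each library so raw counts become reads per million:
#' `rpm = count / library_total * 1e6`. Column sums of the result equal
#' one million.
#'
#' @param x An [abundance_matrix] with unit `"raw_count"`.
#' @return An [abundance_matrix] with unit `"RPM"`.
#' @export
normalize_rpm <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$unit != "raw_count") stop("RPM normalization expects raw counts")
  totals <- colSums(x$values)
  if (any(totals <= 0)) {
    stop("library has zero total counts: ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  }
  out <- x
  out$values <- sweep(x$values, 2L, totals, "/") * 1e6
  out$unit <- "RPM"
  out
}

#' FPKM normalization
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm = count * 1e9 / (length_nt * library_total)`.
#'
#' @param x An [abundance_matrix] with unit `"raw_count"`.
#' @param lengths Optional named vector of feature lengths (nt); defaults
#'   to `x$feature_lengths`.
#' @return An [abundance_matrix] with unit `"FPKM"`.
#' @export
compute_fpkm <- function(x, lengths = NULL) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$unit != "raw_count") stop("FPKM normalization expects raw counts")
  if (is.null(lengths)) lengths <- x$feature_lengths
  if (is.null(lengths)) stop("feature lengths are required for FPKM")
  if (is.null(names(lengths)) && length(lengths) == nrow(x$values)) {
    names(lengths) <- rownames(x$values)
  }
  len <- lengths[rownames(x$values)]
  if (anyNA(len)) {
    stop("missing length for feature(s): ",
         paste(utils::head(rownames(x$values)[is.na(len)], 5L), collapse = ", "))
  }
  if (any(len <= 0)) stop("feature lengths must be positive")
  totals <- colSums(x$values)
  if (any(totals <= 0)) {
    stop("library has zero total counts: ",
         paste(colnames(x$values)[totals <= 0], collapse = ", "))
  }
  out <- x
  out$values <- x$values * 1e9 / outer(as.numeric(len), totals)
  out$unit <- "FPKM"
  out$feature_lengths <- len
  out
}

#' Five-number abundance summary per library
#'
#' Tukey five-number summary (minimum, lower hinge, median, upper hinge,
#' maximum) of each library's abundance distribution, the statistic behind
#' per-library abundance boxplots.
#'
#' @param x An [abundance_matrix] or numeric matrix.
#' @return A 5 x n_libraries matrix with rows min, q1, median, q3, max.
#' @export
abundance_fivenum <- function(x) {
  v <- as_values(x)
  out <- apply(v, 2L, fivenum)
  rownames(out) <- c("min", "q1", "median", "q3", "max")
  out
}
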