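#' Per-feature differential expression across groups
#'
#' Tests every feature for a group effect: a two-sided Welch (unequal
#' variance) t-test for two groups or a classic one-way ANOVA F-test for
#' more than two. By default the test is run on `log2(value + pseudocount)`,
#' which stabilizes the variance of overdispersed abundance data; raw
#' p-values are reported together with Benjamini-Hochberg q-values over
#' the tested features.
#'
#' The log2 fold-change for two-group contrasts is computed on the
#' original scale as `log2((mean1 + pseudocount) / (mean2 + pseudocount))`
#' with group 1 the first factor level. For ANOVA over more than two
#' groups no single fold-change is defined and `log2fc` is `NA`.
#'
#' Features with all-zero values in every tested library get `p = 1` and
#' `log2fc = 0` by convention.
#'
#' @param x An [abundance_matrix] (normalized values recommended) or a
#'   numeric matrix with feature rownames.
#' @param group Factor (or coercible) over the columns of `x`; columns
#'   with `NA` group are dropped. The first level is the numerator of the
#'   fold-change.
#' @param method `"auto"` picks Welch t for 2 groups and ANOVA otherwise.
#' @param pseudocount Added before the log transform and inside the
#'   fold-change ratio. Default 1.
#' @param log_transform Test on log2-transformed values (default TRUE).
#' @param contrast Optional label describing the comparison, stored in the
#'   result (defaults to `"level1_vs_level2"` style).
#' @return Data frame with columns `feature_id`, `contrast`, `log2fc`,
#'   `p_value`, `q_value`, `test`.
#' @export
test_differential <- function(x, group,
                              method = c("auto", "welch_t", "anova"),
                              pseudocount = 1, log_transform = TRUE,
                              contrast = NULL) {
  method <- match.arg(method)
  values <- as_values(x)
  group <- as.factor(group)
  if (length(group) != ncol(values)) {
    stop("`group` must have one entry per library (column)")
  }
  keep <- !is.na(group)
  values <- values[, keep, drop = FALSE]
  group <- droplevels(group[keep])
  ng <- nlevels(group)
  if (ng < 2L) stop("need at least two groups")
  sizes <- table(group)
  if (any(sizes < 2L)) {
    stop("each group needs >= 2 replicates for variance estimation (",
         paste(names(sizes)[sizes < 2L], collapse = ", "), ")")
  }
  if (method == "auto") method <- if (ng == 2L) "welch_t" else "anova"
  if (method == "welch_t" && ng != 2L) stop("welch_t requires exactly 2 groups")

  tv <- if (log_transform) log2(values + pseudocount) else values
  idx1 <- group == levels(group)[1L]
  if (is.null(contrast)) {
    contrast <- if (ng == 2L) {
      paste0(levels(group)[1L], "_vs_", levels(group)[2L])
    } else {
      paste(levels(group), collapse = "|")
    }
  }

  n_feat <- nrow(values)
  p <- numeric(n_feat)
  lfc <- numeric(n_feat)
  for (i in seq_len(n_feat)) {
    raw <- values[i, ]
    if (all(raw == 0)) {
      p[i] <- 1
      lfc[i] <- 0
      next
    }
    v <- tv[i, ]
    if (method == "welch_t") {
      a <- v[idx1]
      b <- v[!idx1]
      p[i] <- tryCatch(
        t.test(a, b)$p.value,
        error = function(e) {
          # both groups (essentially) constant: agree -> no evidence,
          # differ with zero variance -> maximal evidence
          if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
        }
      )
      m1 <- mean(raw[idx1])
      m2 <- mean(raw[!idx1])
      lfc[i] <- log2((m1 + pseudocount) / (m2 + pseudocount))
    } else {
      p[i] <- tryCatch(
        oneway.test(v ~ group, var.equal = TRUE)$p.value,
        error = function(e) 1
      )
      if (is.na(p[i])) {
        gm <- tapply(v, group, mean)
        p[i] <- if (isTRUE(all.equal(max(gm), min(gm)))) 1 else 0
      }
      lfc[i] <- NA_real_
    }
  }
  data.frame(
    feature_id = rownames(values),
    contrast = contrast,
    log2fc = lfc,
    p_value = p,
    q_value = p.adjust(p, method = "BH"),
    test = if (method == "welch_t") "welch_t" else "anova",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
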