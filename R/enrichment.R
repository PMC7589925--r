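#' Hypergeometric term enrichment with rich factors
#'
#' One-sided (upper tail) hypergeometric test of over-representation of a
#' study gene set in each annotation term, the classic GO/pathway
#' enrichment. For a term with `n_term` genes in a population of `N`
#' genes and a study set of `n_study` genes hitting `k` of the term's
#' members, `p = P(X >= k)` with
#' `X ~ Hypergeometric(N, n_term, n_study)`. The rich factor is
#' `k / n_term`, the proportion of the term's genes that are in the study
#' set. Benjamini-Hochberg q-values are computed over the tested terms.
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   the population).
#' @param annotation Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_label`, `namespace`.
#' @param population Character vector defining the gene universe;
#'   defaults to all genes in the annotation. Supply the measured-gene
#'   universe explicitly when appropriate.
#' @param min_size Only terms with at least this many population genes
#'   are tested (default 3).
#' @param report_all Also report terms with no study hit (`k = 0`);
#'   default FALSE.
#' @return Data frame sorted by p-value then decreasing rich factor, with
#'   columns `term_id`, `term_label`, `namespace`, `k`, `n_term`,
#'   `n_study`, `N`, `rich_factor`, `p_value`, `q_value`.
#' @export
enrich_terms <- function(study, annotation, population = NULL,
                         min_size = 3L, report_all = FALSE) {
  stopifnot(all(c("gene_id", "term_id") %in% names(annotation)))
  study <- unique(as.character(study))
  if (is.null(population)) population <- unique(annotation$gene_id)
  population <- unique(as.character(population))
  offenders <- setdiff(study, population)
  if (length(offenders) > 0L) {
    stop("study gene(s) absent from the population: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }
  annotation <- annotation[annotation$gene_id %in% population, , drop = FALSE]
  if (!"term_label" %in% names(annotation)) annotation$term_label <- annotation$term_id
  if (!"namespace" %in% names(annotation)) annotation$namespace <- NA_character_

  members <- lapply(split(annotation$gene_id, annotation$term_id), unique)
  labels <- tapply(annotation$term_label, annotation$term_id,
                   function(x) x[[1L]])
  spaces <- tapply(annotation$namespace, annotation$term_id,
                   function(x) x[[1L]])
  sizes <- lengths(members)
  keep <- sizes >= min_size
  members <- members[keep]
  if (length(members) == 0L) {
    return(data.frame(term_id = character(), term_label = character(),
                      namespace = character(), k = integer(),
                      n_term = integer(), n_study = integer(), N = integer(),
                      rich_factor = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  N <- length(population)
  n_study <- length(study)
  k <- vapply(members, function(g) sum(g %in% study), integer(1L))
  n_term <- lengths(members)
  p <- phyper(k - 1L, n_term, N - n_term, n_study, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(members),
    term_label = as.character(labels[names(members)]),
    namespace = as.character(spaces[names(members)]),
    k = k, n_term = n_term, n_study = n_study, N = N,
    rich_factor = k / n_term,
    p_value = p,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$q_value <- p.adjust(out$p_value, method = "BH")
  if (!report_all) out <- out[out$k > 0L, , drop = FALSE]
  out <- out[order(out$p_value, -out$rich_factor), , drop = FALSE]
  rownames(out) <- NULL
  out
}
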