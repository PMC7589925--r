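#' Define a differential-expression contrast on the grain design
#'
#' Two contrast families are supported:
#' * `stress_response`: one treatment versus control (CG) within a
#'   genotype, pooling time-points; group 1 is the stress treatment.
#' * `genotype`: stress-tolerant (TG) versus stress-sensitive (SG) within
#'   a treatment; group 1 is TG, so "up" means higher in the tolerant
#'   genotype.
#'
#' @param type `"stress_response"` or `"genotype"`.
#' @param genotype Genotype for a stress contrast (`"TG"` or `"SG"`).
#' @param treatment Treatment: the stress arm for `stress_response`
#'   (WS/HS/WH), or the condition under which genotypes are compared for
#'   `genotype`.
#' @return An object of class `de_contrast` with a canonical `label`.
#' @export
de_contrast <- function(type = c("stress_response", "genotype"),
                        genotype = NULL, treatment = NULL) {
  type <- match.arg(type)
  if (type == "stress_response") {
    stopifnot(genotype %in% GENOTYPES,
              treatment %in% setdiff(TREATMENTS, "CG"))
    label <- sprintf("%s:%s_vs_CG", genotype, treatment)
  } else {
    stopifnot(treatment %in% TREATMENTS)
    genotype <- NULL
    label <- sprintf("TG_vs_SG:%s", treatment)
  }
  structure(list(type = type, genotype = genotype, treatment = treatment,
                 label = label),
            class = "de_contrast")
}

#' Parse a contrast label back into a [de_contrast()]
#'
#' @param label A label such as `"TG:WS_vs_CG"` or `"TG_vs_SG:HS"`.
#' @return A `de_contrast` object.
#' @export
parse_contrast <- function(label) {
  m <- regmatches(label, regexec("^(TG|SG):(WS|HS|WH)_vs_CG$", label))[[1L]]
  if (length(m) > 0L) {
    return(de_contrast("stress_response", genotype = m[2L], treatment = m[3L]))
  }
  m <- regmatches(label, regexec("^TG_vs_SG:(CG|WS|HS|WH)$", label))[[1L]]
  if (length(m) > 0L) {
    return(de_contrast("genotype", treatment = m[2L]))
  }
  stop("unrecognized contrast label: ", label)
}

#' Library group assignment for a contrast
#'
#' @param meta Library metadata data frame (with `genotype`,
#'   `treatment`).
#' @param contrast A `de_contrast` (or its label).
#' @return Factor over the rows of `meta`; first level is the contrast's
#'   group 1, `NA` marks libraries outside the contrast.
#' @export
contrast_groups <- function(meta, contrast) {
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  stopifnot(inherits(contrast, "de_contrast"))
  g <- rep(NA_character_, nrow(meta))
  if (contrast$type == "stress_response") {
    in_geno <- meta$genotype == contrast$genotype
    g[in_geno & meta$treatment == contrast$treatment] <- contrast$treatment
    g[in_geno & meta$treatment == "CG"] <- "CG"
    factor(g, levels = c(contrast$treatment, "CG"))
  } else {
    in_trt <- meta$treatment == contrast$treatment
    g[in_trt & meta$genotype == "TG"] <- "TG"
    g[in_trt & meta$genotype == "SG"] <- "SG"
    factor(g, levels = c("TG", "SG"))
  }
}

#' Differential expression for one contrast of an abundance matrix
#'
#' @param x A normalized [abundance_matrix].
#' @param contrast A `de_contrast` or contrast label.
#' @inheritParams test_differential
#' @return [test_differential()] output labelled with the contrast.
#' @export
run_de <- function(x, contrast, pseudocount = 1, log_transform = TRUE) {
  if (is.character(contrast)) contrast <- parse_contrast(contrast)
  stopifnot(inherits(x, "abundance_matrix"))
  groups <- contrast_groups(x$meta, contrast)
  test_differential(x, groups, method = "welch_t", pseudocount = pseudocount,
                    log_transform = log_transform, contrast = contrast$label)
}

#' Step 1: the validated pair universe
#'
#' Combines the three evidence layers into one row per (miRNA, gene)
#' pair: the miRNA must be expressed in the sRNA data, the gene expressed
#' in the transcriptome data (presence rule: maximum abundance above
#' `presence_threshold` in at least one library), and the pair linked by
#' at least one degradome-validated cleavage site. When a miRNA has
#' several validated sites on one gene the best (lowest) category is
#' kept.
#'
#' @param mirna_x,mrna_x Normalized [abundance_matrix] objects used for
#'   the presence rule.
#' @param sites Validated site table from [validate_sites()].
#' @param tx2gene Optional named character vector mapping transcript ids
#'   to gene ids; unmapped transcripts are skipped with a warning.
#'   Default: transcript ids are gene ids.
#' @param presence_threshold Presence floor (default 0).
#' @return Data frame with one row per pair: `mirna_id`, `gene_id`,
#'   `transcript_id`, `site_start`, `cleavage_pos`, `best_category`,
#'   `best_library`.
#' @export
build_validated_pairs <- function(mirna_x, mrna_x, sites, tx2gene = NULL,
                                  presence_threshold = 0) {
  if (nrow(sites) == 0L) return(empty_pair_table())
  if (is.null(tx2gene)) {
    sites$gene_id <- sites$transcript_id
  } else {
    sites$gene_id <- unname(tx2gene[sites$transcript_id])
    if (anyNA(sites$gene_id)) {
      warning(sprintf("skipping %d site(s) with unmappable transcript ids",
                      sum(is.na(sites$gene_id))))
      sites <- sites[!is.na(sites$gene_id), , drop = FALSE]
    }
  }
  mir_present <- rownames(as_values(mirna_x))[
    apply(as_values(mirna_x), 1L, max) > presence_threshold]
  gene_present <- rownames(as_values(mrna_x))[
    apply(as_values(mrna_x), 1L, max) > presence_threshold]
  sites <- sites[sites$mirna_id %in% mir_present &
                   sites$gene_id %in% gene_present, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty_pair_table())
  ord <- order(sites$mirna_id, sites$gene_id, sites$best_category,
               sites$site_start)
  sites <- sites[ord, , drop = FALSE]
  first <- !duplicated(sites[, c("mirna_id", "gene_id")])
  out <- sites[first, c("mirna_id", "gene_id", "transcript_id", "site_start",
                        "cleavage_pos", "best_category", "best_library"),
               drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pair_table <- function() {
  data.frame(mirna_id = character(), gene_id = character(),
             transcript_id = character(), site_start = integer(),
             cleavage_pos = integer(), best_category = integer(),
             best_library = character(), stringsAsFactors = FALSE)
}

empty_module_table <- function() {
  out <- cbind(
    empty_pair_table(),
    data.frame(contrast = character(), mirna_log2fc = numeric(),
               mirna_p = numeric(), mirna_q = numeric(),
               mrna_log2fc = numeric(), mrna_p = numeric(),
               mrna_q = numeric(), stringsAsFactors = FALSE)
  )
  out$direction <- character(0)
  out$antagonistic <- logical(0)
  out
}

#' Step 2: pairs where both members are differentially expressed
#'
#' Keeps pairs whose miRNA and mRNA both reach `p < alpha` in the same
#' contrast, regardless of direction (direction is step 3's job).
#'
#' @param pairs Pair universe from [build_validated_pairs()].
#' @param mirna_de,mrna_de [test_differential()] results for the two
#'   assays; both must carry the same single contrast label.
#' @param alpha Raw p-value threshold (default 0.05). Set
#'   `use_q = TRUE` to filter on BH q-values instead.
#' @param use_q Filter on `q_value` instead of `p_value` (default FALSE).
#' @return `pairs` rows with DE columns attached: `contrast`,
#'   `mirna_log2fc`, `mirna_p`, `mirna_q`, `mrna_log2fc`, `mrna_p`,
#'   `mrna_q`.
#' @export
select_significant_pairs <- function(pairs, mirna_de, mrna_de, alpha = 0.05,
                                     use_q = FALSE) {
  c1 <- unique(mirna_de$contrast)
  c2 <- unique(mrna_de$contrast)
  if (length(c1) != 1L || length(c2) != 1L || !identical(c1, c2)) {
    stop("mirna_de and mrna_de must carry the same single contrast")
  }
  mi <- match(pairs$mirna_id, mirna_de$feature_id)
  gi <- match(pairs$gene_id, mrna_de$feature_id)
  keep <- !is.na(mi) & !is.na(gi)
  pairs <- pairs[keep, , drop = FALSE]
  mi <- mi[keep]
  gi <- gi[keep]
  pairs$contrast <- c1
  pairs$mirna_log2fc <- mirna_de$log2fc[mi]
  pairs$mirna_p <- mirna_de$p_value[mi]
  pairs$mirna_q <- mirna_de$q_value[mi]
  pairs$mrna_log2fc <- mrna_de$log2fc[gi]
  pairs$mrna_p <- mrna_de$p_value[gi]
  pairs$mrna_q <- mrna_de$q_value[gi]
  pm <- if (use_q) pairs$mirna_q else pairs$mirna_p
  pg <- if (use_q) pairs$mrna_q else pairs$mrna_p
  out <- pairs[pm < alpha & pg < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Step 3: keep antagonistic pairs
#'
#' From jointly significant pairs, keeps those in which miRNA and mRNA
#' move in opposite directions (the expected signature of miRNA-guided
#' silencing) and annotates the direction. Pairs with a zero fold-change
#' on either side have no defined direction and are excluded.
#'
#' @param pairs Output of [select_significant_pairs()].
#' @return `pairs` rows that are antagonistic, with `direction`
#'   (`"mirna_up_mrna_down"` / `"mirna_down_mrna_up"`) and
#'   `antagonistic = TRUE`.
#' @export
filter_antagonistic <- function(pairs) {
  if (nrow(pairs) == 0L) {
    pairs$direction <- character(0)
    pairs$antagonistic <- logical(0)
    return(pairs)
  }
  undefined <- pairs$mirna_log2fc == 0 | pairs$mrna_log2fc == 0 |
    is.na(pairs$mirna_log2fc) | is.na(pairs$mrna_log2fc)
  if (any(undefined)) {
    message(sum(undefined), " significant pair(s) with zero/undefined ",
            "fold-change excluded from antagonism")
  }
  keep <- !undefined & pairs$mirna_log2fc * pairs$mrna_log2fc < 0
  out <- pairs[keep, , drop = FALSE]
  out$direction <- ifelse(out$mirna_log2fc > 0,
                          "mirna_up_mrna_down", "mirna_down_mrna_up")
  out$antagonistic <- TRUE
  rownames(out) <- NULL
  out
}

#' Full three-step integration over a set of contrasts
#'
#' Builds the validated pair universe once, then for each contrast runs
#' differential expression on both assays, joint-significance selection
#' (step 2) and the antagonism filter (step 3). A pair may appear under
#' several contrasts.
#'
#' @param mirna_x,mrna_x Normalized [abundance_matrix] objects.
#' @param sites Validated site table from [validate_sites()].
#' @param contrasts List of `de_contrast` objects or contrast labels.
#' @param alpha Significance threshold on raw p (default 0.05).
#' @param use_q Filter on q-values instead (default FALSE).
#' @inheritParams build_validated_pairs
#' @return List with `modules` (antagonistic pairs across contrasts),
#'   `pair_universe`, and per-contrast DE tables in `de_mirna` /
#'   `de_mrna`.
#' @export
run_antagonistic_modules <- function(mirna_x, mrna_x, sites, contrasts,
                                     alpha = 0.05, use_q = FALSE,
                                     tx2gene = NULL, presence_threshold = 0) {
  universe <- build_validated_pairs(mirna_x, mrna_x, sites, tx2gene,
                                    presence_threshold)
  de_mirna <- list()
  de_mrna <- list()
  mods <- list()
  for (ct in contrasts) {
    if (is.character(ct)) ct <- parse_contrast(ct)
    de_m <- run_de(mirna_x, ct)
    de_g <- run_de(mrna_x, ct)
    de_mirna[[ct$label]] <- de_m
    de_mrna[[ct$label]] <- de_g
    sig <- select_significant_pairs(universe, de_m, de_g, alpha = alpha,
                                    use_q = use_q)
    mods[[ct$label]] <- filter_antagonistic(sig)
  }
  modules <- do.call(rbind, mods)
  if (is.null(modules)) modules <- empty_module_table()
  rownames(modules) <- NULL
  list(modules = modules, pair_universe = universe,
       de_mirna = de_mirna, de_mrna = de_mrna)
}

#' Compare recovered modules with the planted truth
#'
#' Recall and precision of recovered antagonistic (miRNA, gene, contrast)
#' triples against a planted truth table.
#'
#' @param modules Module table from [run_antagonistic_modules()].
#' @param truth_pairs `planted_antagonistic_pairs` from the generator
#'   truth (gene ids are transcript ids unless a map was used).
#' @return List with `recall`, `precision`, `n_truth`, `n_found`,
#'   `n_true_positive`.
#' @export
score_recovery <- function(modules, truth_pairs) {
  truth_keys <- unique(paste(truth_pairs$mirna_id, truth_pairs$transcript_id,
                             truth_pairs$contrast, sep = "\r"))
  found_keys <- unique(paste(modules$mirna_id, modules$gene_id,
                             modules$contrast, sep = "\r"))
  tp <- sum(found_keys %in% truth_keys)
  list(
    recall = if (length(truth_keys) == 0L) NA_real_ else tp / length(truth_keys),
    precision = if (length(found_keys) == 0L) NA_real_ else tp / length(found_keys),
    n_truth = length(truth_keys),
    n_found = length(found_keys),
    n_true_positive = tp
  )
}
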