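mirna_ids <- function(n) sprintf("mir_%04d", seq_len(n))
transcript_ids <- function(n) sprintf("tx_%05d", seq_len(n))

random_rna <- function(length) {
  paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
}

#' Simulate a mature miRNA catalog
#'
#' Draws `n_mirna` random RNA sequences with lengths uniform over the
#' plan's length range. Byte-identical under a fixed plan seed.
#'
#' @param plan A [simulation_plan()].
#' @return Named character vector of miRNA sequences (5'->3').
#' @export
simulate_mirnome <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  set.seed(plan$seed)
  n <- plan$n_mirna
  if (n == 0L) return(stats::setNames(character(0), character(0)))
  lens <- sample(seq(plan$mirna_length_range[1L], plan$mirna_length_range[2L]),
                 n, replace = TRUE)
  seqs <- vapply(lens, random_rna, character(1L))
  stats::setNames(seqs, mirna_ids(n))
}

# Which miRNA guides planted pair i. Antagonistic pairs (the first
# n_antagonistic) each get a dedicated miRNA; the remaining pairs cycle
# over the rest of the catalog, so one miRNA may target several mRNAs
# (as in real regulomes) without ever mixing null and planted-effect
# roles for the same miRNA.
pair_mirna_index <- function(i, n_mirna, n_antagonistic) {
  if (i <= n_antagonistic) return(i)
  pool_start <- if (n_antagonistic < n_mirna) n_antagonistic + 1L else 1L
  pool_size <- n_mirna - pool_start + 1L
  pool_start + (i - n_antagonistic - 1L) %% pool_size
}

apply_site_edits <- function(site, mirna, edits) {
  if (length(edits) == 0L) return(site)
  L <- nchar(mirna)
  mc <- seq_chars(mirna)
  sc <- seq_chars(site)
  for (e in edits) {
    p <- e$position
    tpos <- L - p + 1L  # site base opposite miRNA position p
    if (e$type == "mismatch") {
      # the miRNA base itself never pairs with itself (G:G is not a wobble)
      sc[tpos] <- mc[p]
    } else {
      if (mc[p] == "G") {
        sc[tpos] <- "U"
      } else if (mc[p] == "U") {
        sc[tpos] <- "G"
      } else {
        stop(sprintf("GU edit at miRNA position %d impossible: base is %s",
                     p, mc[p]))
      }
    }
  }
  paste(sc, collapse = "")
}

#' Simulate a transcriptome with planted miRNA target sites
#'
#' Generates random background transcripts and embeds, for each planted
#' pair, the reverse complement of the guiding miRNA (with any plan edits
#' applied) at a fixed non-overlapping slot. The recorded cleavage
#' position is the transcript nucleotide opposite miRNA position 10.
#'
#' @param mirnas Named miRNA sequences from [simulate_mirnome()].
#' @param plan A [simulation_plan()].
#' @return List with `transcripts` (named character vector) and `truth`,
#'   a list holding `planted_sites`, `planted_antagonistic_pairs` and
#'   `planted_null_features`.
#' @export
simulate_transcriptome_with_sites <- function(mirnas, plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  set.seed(plan$seed + 1L)
  n_tx <- plan$n_transcript
  tx_len <- plan$transcript_length
  transcripts <- stats::setNames(
    vapply(seq_len(max(n_tx, 0L)), function(i) random_rna(tx_len),
           character(1L)),
    transcript_ids(n_tx)
  )
  n_pairs <- plan$n_planted_pairs
  if (n_pairs == 0L) {
    truth <- list(
      planted_sites = empty_planted_sites(),
      planted_antagonistic_pairs = empty_antagonistic_pairs(),
      planted_null_features = list(mirna = names(mirnas),
                                   transcript = names(transcripts))
    )
    return(list(transcripts = transcripts, truth = truth))
  }
  if (length(mirnas) < plan$n_mirna) {
    stop("miRNA catalog smaller than plan$n_mirna")
  }
  max_len <- plan$mirna_length_range[2L]
  sites <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    tx_idx <- (i - 1L) %% n_tx + 1L
    slot <- (i - 1L) %/% n_tx + 1L
    mir_idx <- pair_mirna_index(i, plan$n_mirna, plan$n_antagonistic)
    mir <- mirnas[[mir_idx]]
    L <- nchar(mir)
    start <- slot_start(slot, max_len)
    site_seq <- apply_site_edits(revcomp_rna(mir), mir, plan$site_edits)
    tx_seq <- transcripts[[tx_idx]]
    substr(tx_seq, start, start + L - 1L) <- site_seq
    transcripts[[tx_idx]] <- tx_seq
    sites[[i]] <- data.frame(
      mirna_id = names(mirnas)[mir_idx],
      transcript_id = names(transcripts)[tx_idx],
      site_start = start,
      site_end = start + L - 1L,
      cleavage_pos = start + L - 10L,
      score_planted = score_duplex(mir, site_seq)$score,
      stringsAsFactors = FALSE
    )
  }
  planted_sites <- do.call(rbind, sites)
  if (any(planted_sites$score_planted >= plan$max_duplex_score)) {
    stop("planted site scores at or above the validation threshold")
  }

  n_anta <- plan$n_antagonistic
  if (n_anta > 0L) {
    combos <- expand.grid(treatment = setdiff(TREATMENTS, "CG"),
                          genotype = GENOTYPES, stringsAsFactors = FALSE)
    idx <- (seq_len(n_anta) - 1L) %% nrow(combos) + 1L
    anta <- data.frame(
      mirna_id = planted_sites$mirna_id[seq_len(n_anta)],
      transcript_id = planted_sites$transcript_id[seq_len(n_anta)],
      contrast = sprintf("%s:%s_vs_CG", combos$genotype[idx],
                         combos$treatment[idx]),
      mirna_direction = sample(c("up", "down"), n_anta, replace = TRUE),
      stringsAsFactors = FALSE
    )
  } else {
    anta <- empty_antagonistic_pairs()
  }
  truth <- list(
    planted_sites = planted_sites,
    planted_antagonistic_pairs = anta,
    planted_null_features = list(
      mirna = setdiff(names(mirnas), anta$mirna_id),
      transcript = setdiff(names(transcripts), anta$transcript_id)
    )
  )
  list(transcripts = transcripts, truth = truth)
}

empty_planted_sites <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             site_start = integer(), site_end = integer(),
             cleavage_pos = integer(), score_planted = numeric(),
             stringsAsFactors = FALSE)
}

empty_antagonistic_pairs <- function() {
  data.frame(mirna_id = character(), transcript_id = character(),
             contrast = character(), mirna_direction = character(),
             stringsAsFactors = FALSE)
}

parse_stress_contrast <- function(label) {
  m <- regmatches(label, regexec("^(TG|SG):(WS|HS|WH)_vs_CG$", label))[[1L]]
  if (length(m) == 0L) stop("unrecognized contrast label: ", label)
  list(genotype = m[2L], treatment = m[3L])
}

#' Simulate negative-binomial expression with planted antagonistic effects
#'
#' Draws raw counts for every feature and library from a negative
#' binomial with a per-feature log-normal baseline mean, a per-library
#' depth factor and a single dispersion. Each planted antagonistic pair
#' multiplies the miRNA mean by `2^(+-effect_log2fc)` in the libraries of
#' its contrast's (genotype, treatment) cell and the target mRNA mean by
#' the opposite factor; all other features keep condition-independent
#' means.
#'
#' @param plan A [simulation_plan()].
#' @param truth Truth list from [simulate_transcriptome_with_sites()].
#' @return List with `mirna` and `mrna` [abundance_matrix] objects (raw
#'   counts); the mRNA matrix carries transcript lengths for FPKM.
#' @export
simulate_expression <- function(plan, truth) {
  stopifnot(inherits(plan, "simulation_plan"))
  set.seed(plan$seed + 2L)
  design <- plan$design
  n_lib <- nrow(design)
  if (n_lib == 0L) stop("design is empty")
  mir_ids <- mirna_ids(plan$n_mirna)
  tx_ids <- transcript_ids(plan$n_transcript)

  mu_mir <- rlnorm(plan$n_mirna, plan$mean_log_mu, plan$mean_log_sd)
  mu_tx <- rlnorm(plan$n_transcript, plan$mean_log_mu, plan$mean_log_sd)
  depth <- rlnorm(n_lib, 0, plan$depth_log_sd)

  mean_mir <- outer(mu_mir, depth)
  mean_tx <- outer(mu_tx, depth)
  dimnames(mean_mir) <- list(mir_ids, design$library_id)
  dimnames(mean_tx) <- list(tx_ids, design$library_id)

  anta <- truth$planted_antagonistic_pairs
  for (j in seq_len(nrow(anta))) {
    ct <- parse_stress_contrast(anta$contrast[j])
    cols <- design$genotype == ct$genotype & design$treatment == ct$treatment
    s <- if (anta$mirna_direction[j] == "up") 1 else -1
    mean_mir[anta$mirna_id[j], cols] <-
      mean_mir[anta$mirna_id[j], cols] * 2^(s * plan$effect_log2fc)
    mean_tx[anta$transcript_id[j], cols] <-
      mean_tx[anta$transcript_id[j], cols] * 2^(-s * plan$effect_log2fc)
  }
  if (!all(is.finite(mean_mir)) || !all(is.finite(mean_tx))) {
    stop("non-finite simulated means")
  }
  size <- 1 / plan$dispersion
  draw <- function(means) {
    m <- matrix(rnbinom(length(means), size = size, mu = means),
                nrow = nrow(means), dimnames = dimnames(means))
    m
  }
  mirna <- abundance_matrix(draw(mean_mir), design, "raw_count")
  lengths <- stats::setNames(rep(plan$transcript_length, plan$n_transcript),
                             tx_ids)
  mrna <- abundance_matrix(draw(mean_tx), design, "raw_count",
                           feature_lengths = lengths)
  list(mirna = mirna, mrna = mrna)
}

#' Simulate degradome tag profiles
#'
#' One degradome library per (genotype, treatment) cell. Every planted
#' cleavage site receives a Poisson tag count whose expectation is
#' `degradome_peak_fraction` times the guiding miRNA's mean raw count in
#' the matching expression libraries (coupling degradome evidence to
#' miRNA abundance); every other position draws background tags at
#' `background_tag_rate` per nucleotide.
#'
#' @param transcripts Named transcript sequences.
#' @param truth Truth list from [simulate_transcriptome_with_sites()].
#' @param mirna_counts miRNA [abundance_matrix] of raw counts from
#'   [simulate_expression()].
#' @param plan A [simulation_plan()].
#' @return Long-format data frame with columns `library_id`,
#'   `transcript_id`, `position`, `count` (zero-count positions omitted).
#' @export
simulate_degradome <- function(transcripts, truth, mirna_counts, plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  set.seed(plan$seed + 3L)
  design <- plan$design
  cells <- unique(design[, c("genotype", "treatment")])
  tx_len <- nchar(transcripts)
  sites <- truth$planted_sites
  if (nrow(sites) > 0L) {
    if (any(sites$cleavage_pos < 1L |
            sites$cleavage_pos > tx_len[sites$transcript_id])) {
      stop("planted cleavage position outside its transcript")
    }
  }
  counts <- mirna_counts$values
  out <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    g <- cells$genotype[ci]
    tr <- cells$treatment[ci]
    lib_id <- sprintf("deg_%s_%s", g, tr)
    cols <- design$genotype == g & design$treatment == tr
    recs <- list()
    if (nrow(sites) > 0L) {
      lam <- plan$degradome_peak_fraction *
        rowMeans(counts[sites$mirna_id, cols, drop = FALSE])
      peak <- rpois(nrow(sites), lam)
      keep <- peak > 0L
      if (any(keep)) {
        recs[[1L]] <- data.frame(
          transcript_id = sites$transcript_id[keep],
          position = sites$cleavage_pos[keep],
          count = peak[keep], stringsAsFactors = FALSE
        )
      }
    }
    if (plan$background_tag_rate > 0) {
      n_bg <- rpois(length(transcripts), plan$background_tag_rate * tx_len)
      has <- which(n_bg > 0L)
      if (length(has) > 0L) {
        bg <- data.frame(
          transcript_id = rep(names(transcripts)[has], n_bg[has]),
          position = unlist(lapply(has, function(i) {
            sample.int(tx_len[i], n_bg[i], replace = TRUE)
          })),
          count = 1L, stringsAsFactors = FALSE
        )
        recs[[length(recs) + 1L]] <- bg
      }
    }
    if (length(recs) == 0L) next
    tab <- do.call(rbind, recs)
    agg <- stats::aggregate(count ~ transcript_id + position, tab, sum)
    agg$library_id <- lib_id
    out[[ci]] <- agg[, c("library_id", "transcript_id", "position", "count")]
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(library_id = character(), transcript_id = character(),
                      position = integer(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$library_id, res$transcript_id, res$position), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$position <- as.integer(res$position)
  res$count <- as.integer(res$count)
  res
}

#' Run the whole generator
#'
#' Convenience wrapper chaining [simulate_mirnome()],
#' [simulate_transcriptome_with_sites()], [simulate_expression()] and
#' [simulate_degradome()] under the plan's seed.
#'
#' @param plan A [simulation_plan()].
#' @return List with `plan`, `mirnas`, `transcripts`, `truth`,
#'   `expression` (list of miRNA/mRNA [abundance_matrix]) and
#'   `degradome` (long tag table).
#' @export
simulate_dataset <- function(plan) {
  mirnas <- simulate_mirnome(plan)
  tx <- simulate_transcriptome_with_sites(mirnas, plan)
  expr <- simulate_expression(plan, tx$truth)
  deg <- simulate_degradome(tx$transcripts, tx$truth, expr$mirna, plan)
  list(plan = plan, mirnas = mirnas, transcripts = tx$transcripts,
       truth = tx$truth, expression = expr, degradome = deg)
}
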