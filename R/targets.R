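# Plant-style duplex scoring (Allen-type rule set): each miRNA position
# contributes 0 for a Watson-Crick pair, `wobble` (default 0.5) for a G:U
# pair and `mismatch` (default 1) otherwise, with penalties doubled over
# the core positions 2-13. Duplexes are gapless; the miRNA is read 5'->3'
# against the target site read 3'->5'.

duplex_penalty_matrix <- function(mismatch = 1, wobble = 0.5) {
  p <- matrix(mismatch, 4L, 4L, dimnames = list(RNA_BASES, RNA_BASES))
  for (b in RNA_BASES) p[b, RNA_COMPLEMENT[b]] <- 0
  p["G", "U"] <- wobble
  p["U", "G"] <- wobble
  p
}

position_weights <- function(L, core = c(2L, 13L)) {
  w <- rep(1, L)
  lo <- max(1L, core[1L])
  hi <- min(L, core[2L])
  if (lo <= hi) w[lo:hi] <- 2
  w
}

#' Score a gapless miRNA/target-site duplex
#'
#' Aligns the miRNA (5'->3') against an equal-length target site on the
#' transcript sense strand (the site's last base pairs miRNA position 1)
#' and scores the duplex with the standard plant penalty scheme: match 0,
#' G:U wobble `wobble`, mismatch `mismatch`, all penalties doubled at
#' miRNA positions `core[1]`-`core[2]`.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (A/C/G/U; T accepted).
#' @param site_seq Target site on the transcript sense strand, 5'->3',
#'   same length as the miRNA.
#' @param mismatch,wobble Base penalties (defaults 1 and 0.5).
#' @param core Integer pair giving the doubled-penalty miRNA positions
#'   (default 2-13).
#' @return An object of class `duplex_alignment`: a list with `score`,
#'   `states` (per miRNA position: match/GU/mismatch), `penalties`, and
#'   the two sequences.
#' @export
score_duplex <- function(mirna_seq, site_seq, mismatch = 1, wobble = 0.5,
                         core = c(2L, 13L)) {
  m <- as_rna(mirna_seq)
  s <- as_rna(site_seq)
  L <- nchar(m)
  if (nchar(s) != L) stop("gapless duplex requires equal-length sequences")
  mc <- seq_chars(m)
  sc <- rev(seq_chars(s))  # sc[i] is the target base opposite miRNA position i
  states <- character(L)
  for (i in seq_len(L)) {
    states[i] <- if (sc[i] == RNA_COMPLEMENT[mc[i]]) {
      "match"
    } else if ((mc[i] == "G" && sc[i] == "U") || (mc[i] == "U" && sc[i] == "G")) {
      "GU"
    } else {
      "mismatch"
    }
  }
  base_pen <- c(match = 0, GU = wobble, mismatch = mismatch)[states]
  pen <- unname(base_pen) * position_weights(L, core)
  structure(
    list(mirna_seq = m, site_seq = s, states = states, penalties = pen,
         score = sum(pen)),
    class = "duplex_alignment"
  )
}

#' @export
print.duplex_alignment <- function(x, ...) {
  glyph <- c(match = "|", GU = "o", mismatch = " ")[x$states]
  cat("miRNA 5' ", x$mirna_seq, " 3'\n", sep = "")
  cat("         ", paste(rev(glyph), collapse = ""), "\n", sep = "")
  cat("site  3' ", paste(rev(seq_chars(x$site_seq)), collapse = ""),
      " 5'   score = ", format(x$score), "\n", sep = "")
  invisible(x)
}

alignment_string <- function(states) {
  paste(c(match = "M", GU = "o", mismatch = "x")[states], collapse = "")
}

#' Scan a transcript for candidate miRNA target sites
#'
#' Slides the miRNA along every window of the transcript, scores each
#' gapless duplex with [score_duplex()]'s scheme, and reports windows at
#' or below `max_score`. Coordinates are 1-based on the transcript sense
#' strand: `site_start` pairs the miRNA 3'-most base, `site_end` pairs
#' miRNA position 1, and `cleavage_pos` is the transcript nucleotide
#' opposite miRNA position 10 (the expected slicing position of the
#' 10-11 duplex center).
#'
#' @param mirna_seq miRNA sequence 5'->3'.
#' @param transcript_seq Transcript sequence 5'->3' (sense strand).
#' @param max_score Report windows with score <= this (default 4.5).
#' @param mirna_id,transcript_id Identifiers carried into the output.
#' @inheritParams score_duplex
#' @return Data frame of candidate sites ordered by score then
#'   coordinate: `mirna_id`, `transcript_id`, `site_start`, `site_end`,
#'   `score`, `cleavage_pos`, `alignment`.
#' @export
scan_transcript <- function(mirna_seq, transcript_seq, max_score = 4.5,
                            mirna_id = "mirna", transcript_id = "transcript",
                            mismatch = 1, wobble = 0.5, core = c(2L, 13L)) {
  m <- as_rna(mirna_seq)
  tx <- as_rna(transcript_seq)
  L <- nchar(m)
  if (nchar(tx) < L) stop("transcript shorter than miRNA")
  scores <- scan_duplex_scores(
    encode_rna(m), encode_rna(tx),
    duplex_penalty_matrix(mismatch, wobble),
    position_weights(L, core)
  )
  hit <- which(scores <= max_score)
  if (length(hit) == 0L) return(empty_site_table())
  aln <- vapply(hit, function(s) {
    alignment_string(score_duplex(m, substr(tx, s, s + L - 1L),
                                  mismatch, wobble, core)$states)
  }, character(1L))
  out <- data.frame(
    mirna_id = mirna_id,
    transcript_id = transcript_id,
    site_start = hit,
    site_end = hit + L - 1L,
    score = scores[hit],
    cleavage_pos = hit + L - 10L,
    alignment = aln,
    stringsAsFactors = FALSE
  )
  out[order(out$score, out$site_start), , drop = FALSE]
}

empty_site_table <- function() {
  data.frame(
    mirna_id = character(), transcript_id = character(),
    site_start = integer(), site_end = integer(), score = numeric(),
    cleavage_pos = integer(), alignment = character(),
    stringsAsFactors = FALSE
  )
}

#' Scan many miRNAs against many transcripts
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @inheritParams scan_transcript
#' @return Combined candidate-site data frame (see [scan_transcript()]).
#' @export
scan_targets <- function(mirnas, transcripts, max_score = 4.5,
                         mismatch = 1, wobble = 0.5, core = c(2L, 13L)) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  pen <- duplex_penalty_matrix(mismatch, wobble)
  mir_codes <- lapply(mirnas, function(m) encode_rna(as_rna(m)))
  tx_codes <- lapply(transcripts, function(tx) encode_rna(as_rna(tx)))
  res <- list()
  for (mi in names(mirnas)) {
    L <- length(mir_codes[[mi]])
    w <- position_weights(L, core)
    for (ti in names(transcripts)) {
      scores <- scan_duplex_scores(mir_codes[[mi]], tx_codes[[ti]], pen, w)
      hit <- which(scores <= max_score)
      if (length(hit) == 0L) next
      aln <- vapply(hit, function(s) {
        alignment_string(score_duplex(
          mirnas[[mi]], substr(transcripts[[ti]], s, s + L - 1L),
          mismatch, wobble, core)$states)
      }, character(1L))
      res[[length(res) + 1L]] <- data.frame(
        mirna_id = mi, transcript_id = ti,
        site_start = hit, site_end = hit + L - 1L,
        score = scores[hit], cleavage_pos = hit + L - 10L,
        alignment = aln, stringsAsFactors = FALSE
      )
    }
  }
  if (length(res) == 0L) return(empty_site_table())
  out <- do.call(rbind, res)
  out <- out[order(out$score, out$mirna_id, out$transcript_id, out$site_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
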