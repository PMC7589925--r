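#' Factorial library design for a grain stress experiment
#'
#' Full crossing of genotype (TG = stress-tolerant, SG = stress-sensitive)
#' by treatment (CG control, WS water deficit, HS heat, WH combined) by
#' developmental time-point (5-45 days post anthesis) with a given number
#' of replicates per cell.
#'
#' @param n_replicates Replicates per design cell (default 3; at least 2
#'   are needed for any differential testing).
#' @param genotypes,treatments,timepoints Factor levels; defaults are the
#'   full grain stress design.
#' @return Data frame with columns `library_id`, `genotype`, `treatment`,
#'   `timepoint_dpa`, `replicate`.
#' @export
grain_design <- function(n_replicates = 3L, genotypes = GENOTYPES,
                         treatments = TREATMENTS,
                         timepoints = TIMEPOINTS_DPA) {
  stopifnot(is_count(n_replicates), n_replicates >= 1L)
  g <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint_dpa = as.integer(timepoints),
                   treatment = treatments, genotype = genotypes,
                   stringsAsFactors = FALSE)
  g <- g[, c("genotype", "treatment", "timepoint_dpa", "replicate")]
  g$library_id <- sprintf("%s%d_%s_r%d", g$genotype, g$timepoint_dpa,
                          g$treatment, g$replicate)
  g[, c("library_id", "genotype", "treatment", "timepoint_dpa", "replicate")]
}

#' Plan for a seeded synthetic multi-omics dataset
#'
#' Collects every knob of the generator that plants known regulatory
#' structure: miRNA and transcript catalog sizes, target-site placement
#' and edits, the factorial expression design, negative-binomial count
#' parameters, the planted antagonistic effect, and the degradome noise
#' model. The plan's defaults define the package's reference simulation
#' scenario (see the methods vignette).
#'
#' @param n_mirna,n_transcript Catalog sizes.
#' @param mirna_length_range Mature miRNA length range in nt, within
#'   18-26 (default 21-24).
#' @param transcript_length Transcript length in nt (default 300; must
#'   leave room for the planted sites).
#' @param n_planted_pairs Number of planted miRNA target sites, each
#'   defining one (miRNA, transcript) pair (default 500).
#' @param n_antagonistic How many planted pairs additionally carry an
#'   antagonistic differential-expression effect (default 50). These
#'   pairs use miRNAs not shared with any other planted site so the
#'   truth table is unambiguous.
#' @param site_edits List of edits applied to every planted site, each a
#'   `list(position = <miRNA position>, type = "mismatch"|"GU")`. The
#'   default (none) plants perfectly complementary sites.
#' @param design Library metadata data frame, normally from
#'   [grain_design()].
#' @param effect_log2fc Planted differential magnitude on the miRNA side
#'   (the mRNA side gets the opposite sign). Default 2.
#' @param dispersion Negative-binomial dispersion (the `1/size`
#'   overdispersion parameter). Default 0.1.
#' @param mean_log_mu,mean_log_sd Log-normal parameters of per-feature
#'   baseline mean counts (defaults `log(200)` and 1).
#' @param depth_log_sd Log-normal spread of per-library sequencing depth
#'   factors (default 0.1).
#' @param degradome_peak_fraction Expected peak tag count at a planted
#'   cleavage site as a fraction of the guiding miRNA's mean count in the
#'   matching condition; in (0, 1] (default 0.25).
#' @param background_tag_rate Expected background degradome tags per
#'   nucleotide per library (default 0.005).
#' @param max_duplex_score Validation threshold the planted sites must
#'   stay strictly below (default 4.5).
#' @param seed Integer seed; every generator stage derives its own
#'   sub-seed from it so each stage is individually reproducible.
#' @return An object of class `simulation_plan`.
#' @export
simulation_plan <- function(n_mirna = 100L,
                            n_transcript = 500L,
                            mirna_length_range = c(21L, 24L),
                            transcript_length = 300L,
                            n_planted_pairs = 500L,
                            n_antagonistic = 50L,
                            site_edits = list(),
                            design = grain_design(3L),
                            effect_log2fc = 2,
                            dispersion = 0.1,
                            mean_log_mu = log(200),
                            mean_log_sd = 1,
                            depth_log_sd = 0.1,
                            degradome_peak_fraction = 0.25,
                            background_tag_rate = 0.005,
                            max_duplex_score = 4.5,
                            seed = 1L) {
  stopifnot(is_count(n_mirna), is_count(n_transcript),
            is_count(n_planted_pairs), is_count(n_antagonistic),
            is_count(transcript_length))
  if (length(mirna_length_range) != 2L ||
      mirna_length_range[1L] > mirna_length_range[2L] ||
      mirna_length_range[1L] < 18L || mirna_length_range[2L] > 26L) {
    stop("mirna_length_range must be an ordered pair within [18, 26]")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be positive")
  }
  if (!is.numeric(degradome_peak_fraction) || degradome_peak_fraction <= 0 ||
      degradome_peak_fraction > 1) {
    stop("degradome_peak_fraction must be in (0, 1]")
  }
  if (background_tag_rate < 0) stop("background_tag_rate must be >= 0")
  if (n_planted_pairs > n_mirna * n_transcript) {
    stop("n_planted_pairs cannot exceed n_mirna * n_transcript")
  }
  if (n_antagonistic > n_planted_pairs) {
    stop("n_antagonistic cannot exceed n_planted_pairs")
  }
  if (n_antagonistic > n_mirna) {
    stop("n_antagonistic cannot exceed n_mirna (antagonistic miRNAs are exclusive)")
  }
  max_len <- mirna_length_range[2L]
  slots <- site_slots(transcript_length, max_len)
  if (n_planted_pairs > 0 && slots < 1L) {
    stop("transcripts too short to host a planted site")
  }
  if (n_planted_pairs > n_transcript * slots) {
    stop(sprintf("cannot place %d non-overlapping sites on %d transcripts of %d nt",
                 n_planted_pairs, n_transcript, transcript_length))
  }
  design <- as.data.frame(design)
  req <- c("library_id", "genotype", "treatment", "timepoint_dpa", "replicate")
  if (!all(req %in% names(design))) {
    stop("design must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(design[, req[-1L]])) {
    stop("(genotype, treatment, timepoint_dpa, replicate) must be unique")
  }
  validate_site_edits(site_edits, mirna_length_range[1L], max_duplex_score)
  structure(
    list(n_mirna = as.integer(n_mirna),
         n_transcript = as.integer(n_transcript),
         mirna_length_range = as.integer(mirna_length_range),
         transcript_length = as.integer(transcript_length),
         n_planted_pairs = as.integer(n_planted_pairs),
         n_antagonistic = as.integer(n_antagonistic),
         site_edits = site_edits,
         design = design,
         effect_log2fc = effect_log2fc,
         dispersion = dispersion,
         mean_log_mu = mean_log_mu,
         mean_log_sd = mean_log_sd,
         depth_log_sd = depth_log_sd,
         degradome_peak_fraction = degradome_peak_fraction,
         background_tag_rate = background_tag_rate,
         max_duplex_score = max_duplex_score,
         seed = as.integer(seed)),
    class = "simulation_plan"
  )
}

# Planted sites are laid out on fixed non-overlapping slots with >= 30 nt
# spacing, keeping the truth table unambiguous for recovery tests.
SITE_SPACING <- 30L

site_slots <- function(transcript_length, max_site_len) {
  max(0L, (transcript_length - SITE_SPACING) %/% (max_site_len + SITE_SPACING))
}

slot_start <- function(slot, max_site_len) {
  SITE_SPACING + (slot - 1L) * (max_site_len + SITE_SPACING) + 1L
}

validate_site_edits <- function(edits, min_mirna_len, max_duplex_score) {
  if (length(edits) == 0L) return(invisible(TRUE))
  pen <- 0
  for (e in edits) {
    if (!is.list(e) || !all(c("position", "type") %in% names(e))) {
      stop("each site edit must be list(position =, type =)")
    }
    if (!e$type %in% c("mismatch", "GU")) {
      stop("edit type must be 'mismatch' or 'GU'")
    }
    if (!is_count(e$position) || e$position < 1L ||
        e$position > min_mirna_len) {
      stop("edit position must fall within every planted miRNA (1..",
           min_mirna_len, ")")
    }
    w <- if (e$position >= 2L && e$position <= 13L) 2 else 1
    pen <- pen + w * if (e$type == "mismatch") 1 else 0.5
  }
  if (pen >= max_duplex_score) {
    stop(sprintf("site edits sum to duplex score %.1f, at or above the validation threshold %.1f",
                 pen, max_duplex_score))
  }
  invisible(TRUE)
}

#' @export
print.simulation_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "simulation_plan: %d miRNAs (%d-%d nt), %d transcripts (%d nt)\n",
    "  planted sites: %d (%d antagonistic, effect %.1f log2 units)\n",
    "  design: %d libraries; NB dispersion %.3g; seed %d\n"),
    x$n_mirna, x$mirna_length_range[1L], x$mirna_length_range[2L],
    x$n_transcript, x$transcript_length,
    x$n_planted_pairs, x$n_antagonistic, x$effect_log2fc,
    nrow(x$design), x$dispersion, x$seed))
  invisible(x)
}
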