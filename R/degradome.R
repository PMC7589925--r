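#' Build a degradome t-plot profile for one transcript
#'
#' Aggregates 5'-end tag records into a dense per-position count vector
#' (the "t-plot" of the transcript). Total tags are conserved.
#'
#' @param tags Data frame with columns `transcript_id`, `position`
#'   (1-based), `count`; extra columns (e.g. `library_id`) are ignored,
#'   so pre-filter to one library if per-library profiles are wanted.
#' @param transcript_id Transcript to profile.
#' @param length Transcript length in nucleotides.
#' @return Integer vector of length `length`; element i is the tag count
#'   whose 5' end maps to position i.
#' @export
build_tplot <- function(tags, transcript_id, length) {
  stopifnot(is_count(length), length >= 1)
  tags <- tags[tags$transcript_id == transcript_id, , drop = FALSE]
  counts <- integer(length)
  if (nrow(tags) == 0L) return(counts)
  pos <- as.integer(tags$position)
  bad <- which(pos < 1L | pos > length)
  if (length(bad) > 0L) {
    stop(sprintf("degradome tag out of range on %s: position %d (length %d)",
                 transcript_id, pos[bad[1L]], length))
  }
  agg <- tapply(as.integer(tags$count), pos, sum)
  counts[as.integer(names(agg))] <- as.integer(agg)
  counts
}

# Category call from sparse summary statistics of the tagged positions:
# c = tag count at the site, max_tag = maximum tag count, n_at_max = how
# many positions attain it, med = median over positions with count > 0.
category_from_stats <- function(c, max_tag, n_at_max, med) {
  if (is.na(c) || c == 0) return(NA_integer_)
  if (c == 1) return(4L)
  if (c == max_tag) {
    if (n_at_max == 1L) 0L else 1L
  } else if (c > med) {
    2L
  } else {
    3L
  }
}

#' Assign a degradome confidence category to a cleavage site
#'
#' Standard category 0-4 classification of a predicted cleavage position
#' against the transcript's t-plot. With `c` the tag count at the site,
#' `M` the maximum count on the transcript and `med` the median count
#' over positions with at least one tag:
#'
#' * category 4: `c == 1` (single read);
#' * category 0: `c > 1`, `c == M`, and the maximum is unique;
#' * category 1: `c > 1`, `c == M`, maximum attained at several positions;
#' * category 2: `c > 1`, `c < M`, `c > med`;
#' * category 3: `c > 1`, `c <= med`;
#' * `NA` ("none"): no tag at the site.
#'
#' The median is taken over tagged positions only, so the call is
#' invariant to padding the profile with zero-count positions.
#'
#' @param profile Integer vector of per-position tag counts (a t-plot,
#'   from [build_tplot()]).
#' @param cleavage_pos 1-based position of the predicted cleavage site.
#' @return Integer category 0-4, or `NA_integer_` for an untagged site.
#' @export
assign_category <- function(profile, cleavage_pos) {
  stopifnot(length(profile) >= 1L, is_count(cleavage_pos),
            cleavage_pos >= 1L, cleavage_pos <= length(profile))
  nz <- profile[profile > 0]
  if (length(nz) == 0L) return(NA_integer_)
  category_from_stats(profile[cleavage_pos], max(nz),
                      sum(nz == max(nz)), median(nz))
}

#' Validate candidate target sites against degradome libraries
#'
#' Assigns a category to every candidate cleavage site in every degradome
#' library and keeps sites whose best (lowest) category over libraries is
#' at most `max_category`. Sites on transcripts outside the profiled id
#' space (when `transcript_lengths` is supplied) are dropped with a
#' warning; sites with no tag in any library are dropped silently
#' (category "none").
#'
#' @param sites Candidate-site data frame from [scan_targets()] (needs
#'   `mirna_id`, `transcript_id`, `cleavage_pos`; other columns are
#'   carried through).
#' @param tags Long-format degradome table with columns `transcript_id`,
#'   `position`, `count` and optionally `library_id` (absent implies a
#'   single library).
#' @param transcript_lengths Optional named vector defining the profiled
#'   transcript universe (used only for the out-of-universe warning).
#' @param max_category Keep sites with best category <= this (default 4,
#'   i.e. any degradome evidence).
#' @return `sites` rows that validate, with added columns
#'   `best_category`, `best_library`, `tag_count` (at the best library)
#'   and `n_libraries_tagged`.
#' @export
validate_sites <- function(sites, tags, transcript_lengths = NULL,
                           max_category = 4L) {
  stopifnot(max_category %in% 0:4)
  if (nrow(sites) == 0L) {
    return(cbind(sites, best_category = integer(), best_library = character(),
                 tag_count = integer(), n_libraries_tagged = integer()))
  }
  if (!"library_id" %in% names(tags)) tags$library_id <- "library_1"
  if (!is.null(transcript_lengths)) {
    known <- names(transcript_lengths)
    missing <- !(sites$transcript_id %in% known)
    if (any(missing)) {
      warning(sprintf("dropping %d site(s) on transcripts absent from the degradome universe (e.g. %s)",
                      sum(missing), sites$transcript_id[which(missing)[1L]]))
      sites <- sites[!missing, , drop = FALSE]
      if (nrow(sites) == 0L) {
        return(cbind(sites, best_category = integer(),
                     best_library = character(), tag_count = integer(),
                     n_libraries_tagged = integer()))
      }
    }
  }
  tags <- tags[tags$count > 0, , drop = FALSE]

  # per (library, transcript) sparse t-plot statistics
  key <- paste(tags$library_id, tags$transcript_id, sep = "\r")
  count_by_pos <- split(
    data.frame(position = as.integer(tags$position),
               count = as.integer(tags$count)),
    key
  )
  stats <- lapply(count_by_pos, function(d) {
    agg <- tapply(d$count, d$position, sum)
    list(pos = as.integer(names(agg)), counts = as.integer(agg),
         max = max(agg), n_at_max = sum(agg == max(agg)),
         med = median(as.integer(agg)))
  })
  libraries <- unique(tags$library_id)

  n <- nrow(sites)
  best_cat <- rep(NA_integer_, n)
  best_lib <- rep(NA_character_, n)
  best_count <- rep(NA_integer_, n)
  n_tagged <- integer(n)
  for (i in seq_len(n)) {
    tx <- sites$transcript_id[i]
    cp <- sites$cleavage_pos[i]
    for (lib in libraries) {
      st <- stats[[paste(lib, tx, sep = "\r")]]
      if (is.null(st)) next
      hit <- match(cp, st$pos)
      if (is.na(hit)) next
      cc <- st$counts[hit]
      n_tagged[i] <- n_tagged[i] + 1L
      cat_i <- category_from_stats(cc, st$max, st$n_at_max, st$med)
      if (is.na(best_cat[i]) || cat_i < best_cat[i]) {
        best_cat[i] <- cat_i
        best_lib[i] <- lib
        best_count[i] <- cc
      }
    }
  }
  out <- sites
  out$best_category <- best_cat
  out$best_library <- best_lib
  out$tag_count <- best_count
  out$n_libraries_tagged <- n_tagged
  out <- out[!is.na(out$best_category) & out$best_category <= max_category, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-site degradome tag matrix across libraries
#'
#' Collects the tag count at each site's cleavage position in every
#' library, the substrate for differential-degradation testing.
#'
#' @inheritParams validate_sites
#' @return Integer matrix, sites x libraries; rownames are
#'   `mirna_id|transcript_id|cleavage_pos`.
#' @export
site_tag_matrix <- function(sites, tags) {
  if (!"library_id" %in% names(tags)) tags$library_id <- "library_1"
  tags <- tags[tags$count > 0, , drop = FALSE]
  libraries <- sort(unique(tags$library_id))
  tag_key <- paste(tags$library_id, tags$transcript_id, tags$position,
                   sep = "\r")
  totals <- tapply(as.integer(tags$count), tag_key, sum)
  out <- matrix(0L, nrow(sites), length(libraries),
                dimnames = list(
                  paste(sites$mirna_id, sites$transcript_id,
                        sites$cleavage_pos, sep = "|"),
                  libraries))
  for (j in seq_along(libraries)) {
    k <- paste(libraries[j], sites$transcript_id, sites$cleavage_pos,
               sep = "\r")
    hit <- totals[k]
    hit[is.na(hit)] <- 0L
    out[, j] <- as.integer(hit)
  }
  out
}

#' Differential degradation of target sites across conditions
#'
#' Normalizes per-site degradome tag counts to reads per million of each
#' library's total degradome tags and applies the same statistical
#' contract as [test_differential()] (Welch t for two groups, one-way
#' ANOVA otherwise, on log2-transformed values).
#'
#' @param site_counts Integer matrix from [site_tag_matrix()] (sites x
#'   libraries).
#' @param group Factor over the libraries (columns).
#' @param library_totals Total degradome tags per library used for the
#'   per-million scaling; defaults to the column sums of `site_counts`.
#' @inheritParams test_differential
#' @return Data frame as returned by [test_differential()].
#' @export
test_differential_degradation <- function(site_counts, group,
                                          library_totals = NULL,
                                          method = c("auto", "welch_t", "anova"),
                                          pseudocount = 1, contrast = NULL) {
  site_counts <- as.matrix(site_counts)
  if (is.null(library_totals)) library_totals <- colSums(site_counts)
  if (any(library_totals <= 0)) {
    stop("library has zero total degradome tags: ",
         paste(colnames(site_counts)[library_totals <= 0], collapse = ", "))
  }
  rpm <- sweep(site_counts, 2L, library_totals, "/") * 1e6
  test_differential(rpm, group, method = method, pseudocount = pseudocount,
                    contrast = contrast)
}
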