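# Independent reference implementations used to cross-check the package.
# These deliberately take the long way round (full enumeration, direct
# summation) and share no code with the implementation under test.

# Degradome category by full enumeration over the dense profile.
oracle_category <- function(profile, pos) {
  c <- profile[pos]
  if (c == 0) return(NA_integer_)
  if (c == 1) return(4L)
  tagged <- sort(profile[profile > 0])
  m <- tagged[length(tagged)]
  med <- stats::median(tagged)
  if (c == m) {
    if (sum(tagged == m) == 1L) 0L else 1L
  } else if (c > med) {
    2L
  } else {
    3L
  }
}

# Duplex score by explicit pair-by-pair lookup against enumerated pair
# sets (no complement table shared with the implementation).
oracle_duplex_score <- function(mirna, site, mismatch = 1, wobble = 0.5) {
  wc <- c("AU", "UA", "GC", "CG")
  gu <- c("GU", "UG")
  m <- strsplit(mirna, "")[[1]]
  s <- strsplit(site, "")[[1]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    pair <- paste0(m[i], s[L - i + 1])
    pen <- if (pair %in% wc) 0 else if (pair %in% gu) wobble else mismatch
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# Hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_p <- function(k, n_term, n_study, N) {
  js <- k:min(n_term, n_study)
  sum(choose(n_term, js) * choose(N - n_term, n_study - js)) /
    choose(N, n_study)
}

random_rna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# Random sparse degradome profile: a dense vector with a handful of
# tagged positions.
random_profile <- function(max_len = 500L) {
  len <- sample(50:max_len, 1L)
  profile <- integer(len)
  n_tag <- sample(1:15, 1L)
  pos <- sample(len, n_tag)
  profile[pos] <- rpois(n_tag, sample(c(0.5, 2, 10), 1L)) + 1L
  profile
}

# Small fast simulation plan for unit tests.
tiny_plan <- function(...) {
  args <- list(...)
  defaults <- list(n_mirna = 8L, n_transcript = 20L, n_planted_pairs = 20L,
                   n_antagonistic = 6L, design = grain_design(2L),
                   seed = 101L)
  defaults[names(args)] <- args
  do.call(simulation_plan, defaults)
}
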