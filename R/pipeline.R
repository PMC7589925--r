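#' End-to-end planted-module recovery on a simulated dataset
#'
#' Runs the full analysis on a [simulation_plan()]: simulate the three
#' omics layers, normalize (RPM for the sRNA assay, FPKM for the mRNA
#' assay), predict target sites by complementarity scanning, validate
#' them against the simulated degradome, run the three-step integration
#' over all six stress-response contrasts, and score the recovered
#' antagonistic modules against the planted truth.
#'
#' @param plan A [simulation_plan()].
#' @param alpha Significance threshold for steps 2-3 (default 0.05).
#' @param max_category Degradome validation cutoff (default 4).
#' @param presence_threshold Expression presence floor (default 0).
#' @return List with `sim`, `sites` (candidates), `validated`, `result`
#'   (from [run_antagonistic_modules()]) and `recovery` (from
#'   [score_recovery()]).
#' @export
run_planted_recovery <- function(plan, alpha = 0.05, max_category = 4L,
                                 presence_threshold = 0) {
  sim <- simulate_dataset(plan)
  mirna_rpm <- normalize_rpm(sim$expression$mirna)
  mrna_fpkm <- compute_fpkm(sim$expression$mrna)
  sites <- scan_targets(sim$mirnas, sim$transcripts,
                        max_score = plan$max_duplex_score)
  lengths <- stats::setNames(nchar(sim$transcripts), names(sim$transcripts))
  validated <- validate_sites(sites, sim$degradome,
                              transcript_lengths = lengths,
                              max_category = max_category)
  grid <- expand.grid(genotype = GENOTYPES,
                      treatment = setdiff(TREATMENTS, "CG"),
                      stringsAsFactors = FALSE)
  contrasts <- lapply(seq_len(nrow(grid)), function(i) {
    de_contrast("stress_response", genotype = grid$genotype[i],
                treatment = grid$treatment[i])
  })
  result <- run_antagonistic_modules(mirna_rpm, mrna_fpkm, validated,
                                     contrasts, alpha = alpha,
                                     presence_threshold = presence_threshold)
  recovery <- score_recovery(result$modules,
                             sim$truth$planted_antagonistic_pairs)
  list(sim = sim, sites = sites, validated = validated, result = result,
       recovery = recovery)
}
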