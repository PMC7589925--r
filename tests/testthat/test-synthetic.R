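test_that("generators are byte-identical under a fixed seed", {
  plan <- tiny_plan()
  sim1 <- simulate_dataset(plan)
  sim2 <- simulate_dataset(plan)
  expect_identical(sim1$mirnas, sim2$mirnas)
  expect_identical(sim1$transcripts, sim2$transcripts)
  expect_identical(sim1$expression$mirna$values, sim2$expression$mirna$values)
  expect_identical(sim1$expression$mrna$values, sim2$expression$mrna$values)
  expect_identical(sim1$degradome, sim2$degradome)

  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_fasta(sim1$mirnas, f1)
  write_fasta(sim2$mirnas, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  sim3 <- simulate_dataset(tiny_plan(seed = 202L))
  expect_false(identical(sim1$mirnas, sim3$mirnas))
})

test_that("miRNA catalog respects size and length constraints", {
  empty <- simulate_mirnome(tiny_plan(n_mirna = 0L, n_planted_pairs = 0L,
                                      n_antagonistic = 0L))
  expect_length(empty, 0L)

  plan <- tiny_plan(n_mirna = 100L, n_transcript = 100L,
                    n_planted_pairs = 0L, n_antagonistic = 0L)
  mirnas <- simulate_mirnome(plan)
  expect_length(mirnas, 100L)
  expect_true(all(nchar(mirnas) %in% 21:24))
  expect_true(all(grepl("^[ACGU]+$", mirnas)))
})

test_that("invalid plan configurations are rejected", {
  expect_error(simulation_plan(mirna_length_range = c(10L, 24L)), "18")
  expect_error(simulation_plan(dispersion = 0), "dispersion")
  expect_error(simulation_plan(degradome_peak_fraction = 1.5), "peak_fraction")
  expect_error(simulation_plan(n_planted_pairs = 11L, n_mirna = 2L,
                               n_transcript = 5L, n_antagonistic = 0L),
               "exceed")
  expect_error(tiny_plan(site_edits = list(list(position = 2L, type = "bogus"))),
               "mismatch")
  # edits that would push planted sites to/above the validation threshold
  heavy <- lapply(2:4, function(p) list(position = p, type = "mismatch"))
  expect_error(tiny_plan(site_edits = heavy, max_duplex_score = 4.5),
               "threshold")
})

test_that("planted sites are perfect complements rediscoverable at score 0", {
  plan <- tiny_plan(n_mirna = 1L, n_transcript = 1L, n_planted_pairs = 1L,
                    n_antagonistic = 0L)
  mirnas <- simulate_mirnome(plan)
  tx <- simulate_transcriptome_with_sites(mirnas, plan)
  site <- tx$truth$planted_sites
  expect_equal(nrow(site), 1L)
  hits <- scan_transcript(mirnas[[1L]], tx$transcripts[[1L]], max_score = 0)
  expect_equal(hits$site_start, site$site_start)
  expect_equal(hits$score, 0)
  expect_equal(hits$cleavage_pos, site$cleavage_pos)
  # cleavage opposite miRNA position 10, inside the site
  expect_equal(site$cleavage_pos, site$site_start + nchar(mirnas[[1L]]) - 10L)
  expect_true(site$cleavage_pos >= site$site_start &&
                site$cleavage_pos <= site$site_end)
})

test_that("site edits change the planted duplex score as specified", {
  plan <- tiny_plan(n_mirna = 1L, n_transcript = 1L, n_planted_pairs = 1L,
                    n_antagonistic = 0L,
                    site_edits = list(list(position = 5L, type = "mismatch")))
  mirnas <- simulate_mirnome(plan)
  tx <- simulate_transcriptome_with_sites(mirnas, plan)
  site <- tx$truth$planted_sites
  # position 5 is in the doubled core: one mismatch scores 2.0
  expect_equal(site$score_planted, 2.0)
  seg <- substr(tx$transcripts[[1L]], site$site_start, site$site_end)
  expect_equal(oracle_duplex_score(mirnas[[1L]], seg), 2.0)
  hits <- scan_transcript(mirnas[[1L]], tx$transcripts[[1L]], max_score = 2)
  expect_true(site$site_start %in% hits$site_start)
})

test_that("zero planted pairs leaves an empty truth table", {
  plan <- tiny_plan(n_planted_pairs = 0L, n_antagonistic = 0L)
  tx <- simulate_transcriptome_with_sites(simulate_mirnome(plan), plan)
  expect_equal(nrow(tx$truth$planted_sites), 0L)
  expect_equal(nrow(tx$truth$planted_antagonistic_pairs), 0L)
})

test_that("planted differential effects are detectable at 3 replicates per cell", {
  # effect_log2fc = 2, dispersion = 0.1, n = 3: at least 90% of planted
  # miRNAs should be called DEM at p < 0.05 in their own contrast
  plan <- simulation_plan(n_mirna = 300L, n_transcript = 300L,
                          n_planted_pairs = 300L, n_antagonistic = 300L,
                          design = grain_design(3L, timepoints = 5L),
                          effect_log2fc = 2, dispersion = 0.1, seed = 3L)
  mirnas <- simulate_mirnome(plan)
  tx <- simulate_transcriptome_with_sites(mirnas, plan)
  expr <- simulate_expression(plan, tx$truth)
  mirna_rpm <- normalize_rpm(expr$mirna)
  anta <- tx$truth$planted_antagonistic_pairs
  hits <- 0L
  for (ct in unique(anta$contrast)) {
    de <- run_de(mirna_rpm, ct)
    sel <- anta$contrast == ct
    hits <- hits +
      sum(de$p_value[match(anta$mirna_id[sel], de$feature_id)] < 0.05)
  }
  expect_gte(hits / nrow(anta), 0.9)
})

test_that("antagonistic planting couples the two assays in opposite directions", {
  plan <- tiny_plan(n_antagonistic = 6L, effect_log2fc = 3)
  sim <- simulate_dataset(plan)
  anta <- sim$truth$planted_antagonistic_pairs
  expect_true(all(anta$mirna_direction %in% c("up", "down")))
  mirna_rpm <- normalize_rpm(sim$expression$mirna)
  mrna_fpkm <- compute_fpkm(sim$expression$mrna)
  for (j in seq_len(nrow(anta))) {
    de_m <- run_de(mirna_rpm, anta$contrast[j])
    de_g <- run_de(mrna_fpkm, anta$contrast[j])
    lfc_m <- de_m$log2fc[de_m$feature_id == anta$mirna_id[j]]
    lfc_g <- de_g$log2fc[de_g$feature_id == anta$transcript_id[j]]
    expect_lt(lfc_m * lfc_g, 0)
    expect_equal(unname(sign(lfc_m)),
                 if (anta$mirna_direction[j] == "up") 1 else -1)
  }
})

test_that("zero-background degradome gives category 0 at every expressed planted site", {
  plan <- tiny_plan(background_tag_rate = 0, mean_log_sd = 0)
  sim <- simulate_dataset(plan)
  expect_gt(nrow(sim$degradome), 0L)
  # all tags sit exactly on planted cleavage positions
  keys <- paste(sim$degradome$transcript_id, sim$degradome$position)
  planted <- paste(sim$truth$planted_sites$transcript_id,
                   sim$truth$planted_sites$cleavage_pos)
  expect_true(all(keys %in% planted))
  for (lib in unique(sim$degradome$library_id)) {
    tags <- sim$degradome[sim$degradome$library_id == lib, ]
    for (txid in unique(tags$transcript_id)) {
      profile <- build_tplot(tags, txid, nchar(sim$transcripts[[txid]]))
      cp <- sim$truth$planted_sites$cleavage_pos[
        sim$truth$planted_sites$transcript_id == txid]
      expect_equal(assign_category(profile, cp), 0L)
    }
  }
})

test_that("simulated dataset round-trips through its file artifacts", {
  plan <- tiny_plan()
  sim <- simulate_dataset(plan)
  outdir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, outdir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_fasta(paths[["mirna_fasta"]]), sim$mirnas)
  expect_equal(read_counts_tsv(paths[["mirna_counts"]]),
               sim$expression$mirna$values)
  meta <- read_library_meta(paths[["library_meta"]])
  expect_equal(meta$library_id, sim$plan$design$library_id)
  deg <- read_degradome_tsv(paths[["degradome"]])
  expect_equal(deg$count, sim$degradome$count)
})
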