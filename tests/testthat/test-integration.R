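de_table <- function(ids, lfc, p, contrast = "TG:WS_vs_CG") {
  data.frame(feature_id = ids, contrast = contrast, log2fc = lfc,
             p_value = p, q_value = p.adjust(p, "BH"), test = "welch_t",
             stringsAsFactors = FALSE)
}

sites_table <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  defaults <- list(site_start = 10L, cleavage_pos = 21L, best_category = 0L,
                   best_library = "d1")
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  df
}

expr_am <- function(values) {
  abundance_matrix(values, data.frame(library_id = colnames(values)), "RPM")
}

test_that("pair universe requires expression of both members and deduplicates sites", {
  sites <- sites_table(
    mirna_id = c("m1", "m1", "m2", "m3"),
    transcript_id = c("t1", "t1", "t2", "t3"),
    site_start = c(10L, 60L, 10L, 10L),
    cleavage_pos = c(21L, 71L, 21L, 21L),
    best_category = c(2L, 0L, 1L, 0L)
  )
  mirna <- expr_am(matrix(c(5, 3, 8, 2, 0, 0), 3, 2, byrow = TRUE,
                          dimnames = list(c("m1", "m2", "m3"), c("a", "b"))))
  mrna <- expr_am(matrix(c(4, 4, 9, 1, 7, 2), 3, 2, byrow = TRUE,
                         dimnames = list(c("t1", "t2", "t3"), c("a", "b"))))
  pairs <- build_validated_pairs(mirna, mrna, sites)
  # m3 never expressed -> its pair is excluded despite the validated site
  expect_setequal(pairs$mirna_id, c("m1", "m2"))
  # two sites of m1 on t1 collapse to one pair with the best category
  m1 <- pairs[pairs$mirna_id == "m1", ]
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$best_category, 0L)
  expect_equal(m1$site_start, 60L)

  # transcript-to-gene collapsing with an explicit map
  mrna_g <- expr_am(matrix(c(4, 4), 1, 2,
                           dimnames = list("GENE1", c("a", "b"))))
  mapped <- build_validated_pairs(mirna, mrna_g, sites[1:2, ],
                                  tx2gene = c(t1 = "GENE1"))
  expect_equal(mapped$gene_id, "GENE1")
  expect_warning(
    build_validated_pairs(mirna, mrna_g, sites, tx2gene = c(t1 = "GENE1")),
    "unmappable")
})

test_that("joint significance keeps pairs only when both sides pass", {
  pairs <- sites_table(mirna_id = c("m1", "m2", "m3"),
                       transcript_id = c("t1", "t2", "t3"))
  pairs$gene_id <- pairs$transcript_id
  mirna_de <- de_table(c("m1", "m2", "m3"), c(-1.2, 1.0, 0.9),
                       c(0.01, 0.01, 0.2))
  mrna_de <- de_table(c("t1", "t2", "t3"), c(0.8, 0.7, -2.0),
                      c(0.03, 0.2, 0.01))
  sig <- select_significant_pairs(pairs, mirna_de, mrna_de, alpha = 0.05)
  # m1/t1 both significant; m2's mRNA and m3's miRNA are not
  expect_equal(sig$mirna_id, "m1")
  expect_equal(sig$mirna_log2fc, -1.2)
  expect_equal(sig$mrna_p, 0.03)

  # direction is irrelevant at step 2
  mrna_de2 <- de_table(c("t1", "t2", "t3"), c(-0.8, 0.7, -2.0),
                       c(0.03, 0.2, 0.01))
  expect_equal(select_significant_pairs(pairs, mirna_de, mrna_de2)$mirna_id,
               "m1")

  # mismatched contrasts are an error
  bad <- de_table(c("t1", "t2", "t3"), c(0.8, 0.7, -2.0), c(0.03, 0.2, 0.01),
                  contrast = "SG:HS_vs_CG")
  expect_error(select_significant_pairs(pairs, mirna_de, bad), "contrast")

  # shrinking alpha never adds pairs
  strict <- select_significant_pairs(pairs, mirna_de, mrna_de, alpha = 0.01)
  expect_true(all(strict$mirna_id %in% sig$mirna_id))
})

test_that("antagonism keeps opposite-sign pairs and annotates direction", {
  pairs <- sites_table(mirna_id = c("m1", "m2", "m3"),
                       transcript_id = c("t1", "t2", "t3"))
  pairs$gene_id <- pairs$transcript_id
  mirna_de <- de_table(c("m1", "m2", "m3"), c(-1.2, 1.1, 0.5),
                       c(0.01, 0.02, 0.01))
  mrna_de <- de_table(c("t1", "t2", "t3"), c(0.8, 0.9, 0),
                      c(0.03, 0.03, 0.01))
  sig <- select_significant_pairs(pairs, mirna_de, mrna_de)
  expect_equal(nrow(sig), 3L)
  anta <- suppressMessages(filter_antagonistic(sig))
  # m1 down / t1 up antagonistic; m2/t2 both up dropped; m3/t3 zero lfc dropped
  expect_equal(anta$mirna_id, "m1")
  expect_equal(anta$direction, "mirna_down_mrna_up")
  expect_true(all(anta$antagonistic))
  expect_true(all(sign(anta$mirna_log2fc) * sign(anta$mrna_log2fc) < 0))
})

test_that("three-step integration recovers planted modules on a small simulation", {
  plan <- tiny_plan(n_mirna = 30L, n_transcript = 60L, n_planted_pairs = 60L,
                    n_antagonistic = 20L, design = grain_design(3L),
                    seed = 55L)
  out <- run_planted_recovery(plan)
  expect_gte(out$recovery$recall, 0.9)
  expect_gte(out$recovery$precision, 0.8)
  # soundness: every module satisfies the three step predicates
  mods <- out$result$modules
  expect_true(all(mods$best_category <= 4L))
  expect_true(all(mods$mirna_p < 0.05 & mods$mrna_p < 0.05))
  expect_true(all(mods$mirna_log2fc * mods$mrna_log2fc < 0))
  # every module pair exists in the validated universe
  expect_true(all(paste(mods$mirna_id, mods$gene_id) %in%
                    paste(out$result$pair_universe$mirna_id,
                          out$result$pair_universe$gene_id)))
})

test_that("genotype contrasts follow the tolerant-over-sensitive convention", {
  plan <- tiny_plan(n_antagonistic = 0L, seed = 60L)
  sim <- simulate_dataset(plan)
  mirna_rpm <- normalize_rpm(sim$expression$mirna)
  # plant a genotype effect by hand: higher in TG under WS
  up_id <- rownames(mirna_rpm$values)[1L]
  cols <- mirna_rpm$meta$genotype == "TG" & mirna_rpm$meta$treatment == "WS"
  mirna_rpm$values[up_id, cols] <- mirna_rpm$values[up_id, cols] * 8
  de <- run_de(mirna_rpm, de_contrast("genotype", treatment = "WS"))
  expect_equal(unique(de$contrast), "TG_vs_SG:WS")
  expect_gt(de$log2fc[de$feature_id == up_id], 0)
  expect_lt(de$p_value[de$feature_id == up_id], 0.05)
})

test_that("network export round-trips and handles empty module sets", {
  outdir <- withr::local_tempdir()
  files <- export_network(empty_mods <- data.frame(), outdir)
  expect_true(all(file.exists(files)))
  empty_edges <- read_network_edges(file.path(outdir, "modules_all.tsv"))
  expect_equal(nrow(empty_edges), 0L)
  expect_true(all(c("mirna_id", "gene_id", "direction") %in%
                    names(empty_edges)))

  plan <- tiny_plan(n_mirna = 12L, n_transcript = 30L, n_planted_pairs = 30L,
                    n_antagonistic = 8L, design = grain_design(3L),
                    seed = 55L)
  out <- run_planted_recovery(plan)
  mods <- out$result$modules
  outdir2 <- withr::local_tempdir()
  files2 <- export_network(mods, outdir2)
  edges <- do.call(rbind, lapply(grep("modules_", files2, value = TRUE),
                                 read_network_edges))
  expect_equal(nrow(edges), nrow(mods))
  expect_setequal(paste(edges$mirna_id, edges$gene_id, edges$contrast),
                  paste(mods$mirna_id, mods$gene_id, mods$contrast))
  expect_equal(sort(unique(edges$direction)), sort(unique(mods$direction)))

  nodes <- read.delim(file.path(outdir2, "nodes.tsv"))
  expect_setequal(nodes$node_id[nodes$role == "miRNA"], unique(mods$mirna_id))

  # per-treatment direction glyphs match the planted effects
  dirs <- read.delim(file.path(outdir2, "directions.tsv"))
  anta <- out$sim$truth$planted_antagonistic_pairs
  recovered <- merge(anta, dirs,
                     by.x = c("mirna_id", "transcript_id"),
                     by.y = c("mirna_id", "gene_id"))
  for (i in seq_len(nrow(recovered))) {
    tr <- sub("^(TG|SG):(WS|HS|WH)_vs_CG$", "\\2", recovered$contrast[i])
    expect_equal(recovered[[tr]][i], recovered$mirna_direction[i])
  }
  json <- jsonlite::read_json(file.path(outdir2, "network.json"))
  expect_equal(length(json$edges), nrow(mods))
})
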