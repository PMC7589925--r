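# Plain-text readers/writers for the pipeline's artifact dialects.
# Sequence files go through Biostrings; tables are plain TSV.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file. DNA alphabet (T) is converted to RNA (U).
#' @return Named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as_rna(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Write a counts TSV (feature_id column, one column per library)
#' @param x An [abundance_matrix] or matrix with feature rownames.
#' @param path Output file.
#' @export
write_counts_tsv <- function(x, path) {
  v <- as_values(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a counts TSV written by [write_counts_tsv()]
#' @param path Input file.
#' @return Numeric matrix with feature rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Write library metadata TSV
#' @param meta Library metadata data frame.
#' @param path Output file.
#' @export
write_library_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read library metadata TSV
#' @param path Input file.
#' @return Data frame of library metadata.
#' @export
read_library_meta <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a long-format degradome tag table
#' @param tags Data frame (`library_id`, `transcript_id`, `position`,
#'   `count`).
#' @param path Output file.
#' @export
write_degradome_tsv <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format degradome tag table
#' @param path Input file.
#' @return Data frame with `transcript_id`, `position`, `count` and
#'   (if present) `library_id`.
#' @export
read_degradome_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write a simulated dataset's artifacts to a directory
#'
#' Writes miRNA and transcript FASTA, raw count TSVs, library metadata,
#' the degradome tag table and the ground truth (JSON).
#'
#' @param sim Output of [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_dataset <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    mirna_fasta = file.path(outdir, "mirna.fa"),
    transcript_fasta = file.path(outdir, "transcripts.fa"),
    mirna_counts = file.path(outdir, "mirna_counts.tsv"),
    mrna_counts = file.path(outdir, "mrna_counts.tsv"),
    library_meta = file.path(outdir, "library_meta.tsv"),
    degradome = file.path(outdir, "degradome_tags.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_fasta(sim$mirnas, paths[["mirna_fasta"]])
  write_fasta(sim$transcripts, paths[["transcript_fasta"]])
  write_counts_tsv(sim$expression$mirna, paths[["mirna_counts"]])
  write_counts_tsv(sim$expression$mrna, paths[["mrna_counts"]])
  write_library_meta(sim$plan$design, paths[["library_meta"]])
  write_degradome_tsv(sim$degradome, paths[["degradome"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Export antagonistic modules as network artifacts
#'
#' Writes, under `outdir`:
#' * `modules_<contrast>.tsv` - one edge list per contrast with both
#'   fold-changes, p-values, degradome category and direction;
#' * `nodes.tsv` - node table with role labels (miRNA / gene);
#' * `directions.tsv` - per-pair, per-treatment miRNA direction glyphs
#'   (`up` / `down` / `ns`), the tabular form of per-condition arrow
#'   annotations on network figures;
#' * `network.json` - nodes plus edges in one JSON document.
#'
#' @param pairs Module table from [run_antagonistic_modules()] (possibly
#'   empty).
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
export_network <- function(pairs, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(pairs) == 0L) pairs <- empty_module_table()
  edge_cols <- c("mirna_id", "gene_id", "contrast", "direction",
                 "best_category", "mirna_log2fc", "mirna_p", "mrna_log2fc",
                 "mrna_p")
  files <- character(0)
  contrasts <- unique(pairs$contrast)
  if (length(contrasts) == 0L) contrasts <- "all"
  for (ct in contrasts) {
    sel <- if (identical(ct, "all")) pairs else
      pairs[pairs$contrast == ct, , drop = FALSE]
    f <- file.path(outdir,
                   sprintf("modules_%s.tsv", gsub("[^A-Za-z0-9_]+", "_", ct)))
    write.table(sel[, edge_cols, drop = FALSE], f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  mir_nodes <- unique(pairs$mirna_id)
  gene_nodes <- unique(pairs$gene_id)
  nodes <- data.frame(
    node_id = c(mir_nodes, gene_nodes),
    role = c(rep("miRNA", length(mir_nodes)), rep("gene", length(gene_nodes))),
    stringsAsFactors = FALSE
  )
  node_file <- file.path(outdir, "nodes.tsv")
  write.table(nodes, node_file, sep = "\t", quote = FALSE, row.names = FALSE)
  dir_file <- file.path(outdir, "directions.tsv")
  write.table(direction_table(pairs), dir_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  json_file <- file.path(outdir, "network.json")
  jsonlite::write_json(
    list(nodes = nodes, edges = pairs[, edge_cols, drop = FALSE]),
    json_file, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(c(files, node_file, dir_file, json_file))
}

#' Per-treatment miRNA direction glyph table
#'
#' One row per (miRNA, gene) pair, one column per stress treatment;
#' entries are `"up"` / `"down"` when the pair is antagonistic under that
#' treatment's contrast (direction of the miRNA) and `"ns"` otherwise.
#'
#' @param pairs Module table with stress-response contrasts.
#' @return Data frame with `mirna_id`, `gene_id` and one column per
#'   treatment (WS, HS, WH).
#' @export
direction_table <- function(pairs) {
  treatments <- setdiff(TREATMENTS, "CG")
  ids <- unique(pairs[, c("mirna_id", "gene_id"), drop = FALSE])
  out <- ids
  for (tr in treatments) out[[tr]] <- rep("ns", nrow(ids))
  if (nrow(pairs) == 0L) return(out)
  for (i in seq_len(nrow(pairs))) {
    ct <- pairs$contrast[i]
    tr <- sub("^(TG|SG):(WS|HS|WH)_vs_CG$", "\\2", ct)
    if (!tr %in% treatments) next
    row <- which(out$mirna_id == pairs$mirna_id[i] &
                   out$gene_id == pairs$gene_id[i])
    out[[tr]][row] <- if (pairs$mirna_log2fc[i] > 0) "up" else "down"
  }
  out
}

#' Read a module edge list back
#'
#' @param path A `modules_*.tsv` file from [export_network()].
#' @return Data frame of edges.
#' @export
read_network_edges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
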