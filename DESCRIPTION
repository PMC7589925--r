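Package: triomirnet
Title: Integration of Small RNA, Transcriptome and Degradome Data into
    miRNA-mRNA Regulatory Modules
Version: 0.9.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering antagonistic miRNA-mRNA regulatory
    modules in factorial stress-by-development expression designs, such as
    developing cereal grain under water deficit and heat stress.
    Implements reads-per-million and FPKM normalization, Welch t and
    one-way ANOVA differential expression with Benjamini-Hochberg
    correction, plant-style miRNA target-site scoring with G:U wobble
    penalties, degradome (PARE) t-plot construction with category 0-4
    cleavage-site classification, hypergeometric term enrichment with
    rich factors, a three-step multi-omics integration yielding
    antagonistic miRNA-mRNA pairs, and a seeded negative-binomial
    simulator that plants known regulatory structure for end-to-end
    validation.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
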