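# RNA alphabet used throughout; readers convert DNA T to U on input.
RNA_BASES <- c("A", "C", "G", "U")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

GENOTYPES <- c("TG", "SG")
TREATMENTS <- c("CG", "WS", "HS", "WH")
TIMEPOINTS_DPA <- c(5L, 15L, 25L, 35L, 45L)

#' Convert a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and replaces T with U. Any character outside A/C/G/U after
#' conversion is an error.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over the alphabet A, C, G, U.
#' @export
as_rna <- function(x) {
  out <- chartr("acgtu", "ACGUU", chartr("T", "U", toupper(x)))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    stop("sequence(s) contain characters outside the RNA alphabet: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  out
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Reverse complement of an RNA sequence
#'
#' @param x A single RNA sequence (character scalar, A/C/G/U).
#' @return The reverse complement as a character scalar.
#' @export
revcomp_rna <- function(x) {
  ch <- seq_chars(as_rna(x))
  paste(rev(unname(RNA_COMPLEMENT[ch])), collapse = "")
}

# Encode an RNA string as integer codes 1..4 (A,C,G,U) for the scan kernel.
encode_rna <- function(x) {
  codes <- match(seq_chars(x), RNA_BASES)
  if (anyNA(codes)) stop("invalid RNA alphabet in sequence")
  codes
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == as.integer(x)
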