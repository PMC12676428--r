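#' @useDynLib piswarm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# quiet R CMD check notes about data.table NSE columns
utils::globalVariables(c(
  ".", ".N", "count", "gene_id", "kmer", "pos", "seed_off", "window_id",
  "sequence", "weight", "fraction", "source_label", "chrom", "start",
  "end", "strand", "five_prime", "tx_id", "n_genes", "weight_share",
  "n_hits", "share", "pirna", "mismatch_count", "mismatch_positions",
  "slice_pos", "span_nt", "n_unique_pirnas", "rank", "ex_start", "ex_end"
))

#' Reverse complement of DNA strings
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequence
#'
#' @param n sequence length in nt.
#' @param gc GC content (probability of G or C per base).
#' @return a single DNA string.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Hamming mismatch count between equal-length string vectors (vectorised in C).
hamming_vec <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  hamming_pairs_cpp(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
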