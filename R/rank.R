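#' Fraction of the piRNA pool that targets mRNAs
#'
#' Summed read count of pool records with at least one target site, divided
#' by total pool reads.
#'
#' @param pool a `pirna_pool`.
#' @param site_table site table from [match_pool()] derived from `pool`.
#' @return scalar proportion in `[0, 1]`.
#' @export
targeting_fraction <- function(pool, site_table) {
  if (pool$total_reads == 0L) stop("targeting_fraction: empty pool")
  targeting <- unique(site_table$pirna)
  sel <- pool$records$sequence %in% targeting
  sum(pool$records$count[sel]) / pool$total_reads
}

#' Aggregate targeting piRNA weight by gene and rank targets
#'
#' Each piRNA's read count is distributed over the genes it targets. Policy
#' `"split"` (default) divides the weight equally among targeted genes so
#' fractions are proportions of the targeting pool; `"full"` credits the full
#' weight to every targeted gene and renormalises. Ranks are assigned by
#' descending fraction with ties broken lexicographically by `gene_id`.
#'
#' @param site_table site table from [match_pool()].
#' @param policy `"split"` or `"full"`.
#' @return rank table: data.frame with `gene_id`, `weight`, `fraction`,
#'   `rank`, `span_nt` (size of the union of site intervals on the
#'   transcript), `n_unique_pirnas`.
#' @export
aggregate_by_gene <- function(site_table, policy = c("split", "full")) {
  policy <- match.arg(policy)
  if (nrow(site_table) == 0L) stop("aggregate_by_gene: empty site table")
  dt <- data.table::as.data.table(site_table)
  # one weight entry per (pirna, gene); sites within a gene do not multiply weight
  pg <- unique(dt[, .(pirna, gene_id, count)])
  pg[, n_genes := .N, by = pirna]
  pg[, weight := if (policy == "split") count / n_genes else as.numeric(count)]
  by_gene <- pg[, .(weight = sum(weight), n_unique_pirnas = .N), by = gene_id]
  span <- dt[, .(span_nt = {
    ir <- IRanges::reduce(IRanges::IRanges(start, end))
    sum(IRanges::width(ir))
  }), by = gene_id]
  out <- merge(by_gene, span, by = "gene_id")
  out[, fraction := weight / sum(weight)]
  data.table::setorder(out, -fraction, gene_id)
  out[, rank := .I]
  as.data.frame(out[, .(gene_id, weight, fraction, rank, span_nt, n_unique_pirnas)])
}

#' Top-target set by cumulative coverage
#'
#' Smallest rank prefix whose cumulative fraction of targeting weight reaches
#' `coverage`.
#'
#' @param rank_table output of [aggregate_by_gene()].
#' @param coverage proportion in `(0, 1]`.
#' @return character vector of gene ids (in rank order).
#' @export
top_target_set <- function(rank_table, coverage = 0.70) {
  stopifnot(coverage > 0, coverage <= 1)
  rt <- rank_table[order(rank_table$rank), ]
  cum <- cumsum(rt$fraction)
  n <- which(cum >= coverage - 1e-12)[1]
  if (is.na(n)) n <- nrow(rt)
  rt$gene_id[seq_len(n)]
}

#' Metagene profile of piRNA 5'-end positions
#'
#' For each site, the transcript coordinate paired to the piRNA 5' end (the
#' last base of the site interval, since the piRNA lies antisense) is
#' assigned to its transcript feature and to bin
#' `floor(n_bins * offset / feature_length) + 1` within that feature. Each
#' gene's `3 * n_bins` vector is normalised to sum 1 (read-count weighted)
#' and vectors are averaged across genes. Genes lacking any of the three
#' features are excluded (and reported in the `excluded` attribute).
#'
#' @param site_table site table from [match_pool()].
#' @param transcripts named list of `transcript_seq`.
#' @param genes genes to average over (default: all genes in the site table).
#' @param n_bins bins per feature.
#' @return matrix `3 x n_bins` (rows `5UTR`, `CDS`, `3UTR`) of mean per-bin
#'   fractions, with attributes `n_genes` and `excluded`.
#' @export
metagene_profile <- function(site_table, transcripts, genes = NULL, n_bins = 20L) {
  if (is.null(genes)) genes <- unique(site_table$gene_id)
  feat_names <- c("5UTR", "CDS", "3UTR")
  acc <- matrix(0, 3L, n_bins, dimnames = list(feat_names, seq_len(n_bins)))
  used <- 0L
  excluded <- character(0)
  for (g in genes) {
    tx <- transcripts[[g]]
    if (is.null(tx) || !tx$has_cds || tx$utr5_len == 0L || tx$cds_len == 0L ||
        tx$utr3_len == 0L) {
      excluded <- c(excluded, g)
      next
    }
    st <- site_table[site_table$gene_id == g, , drop = FALSE]
    if (nrow(st) == 0L) { excluded <- c(excluded, g); next }
    pos <- st$end # transcript coordinate paired to the piRNA 5' end
    flen <- c(tx$utr5_len, tx$cds_len, tx$utr3_len)
    fstart <- cumsum(c(0L, flen[-3]))
    fi <- findInterval(pos - 1L, cumsum(c(0L, flen)), rightmost.closed = FALSE)
    fi[fi > 3L] <- 3L
    off <- pos - 1L - fstart[fi]
    bin <- pmin(floor(n_bins * off / flen[fi]), n_bins - 1L) + 1L
    v <- matrix(0, 3L, n_bins)
    for (i in seq_along(pos)) v[fi[i], bin[i]] <- v[fi[i], bin[i]] + st$count[i]
    acc <- acc + v / sum(v)
    used <- used + 1L
  }
  if (used == 0L) stop("metagene_profile: no eligible genes")
  out <- acc / used
  attr(out, "n_genes") <- used
  attr(out, "excluded") <- excluded
  out
}

#' Scale a pool fraction to molecules per cell
#'
#' @param fraction proportion in `[0, 1]`.
#' @param total_per_cell total piRNA molecules per cell (default `1e7`).
#' @param round_thousand round the result to the nearest thousand.
#' @return molecule count.
#' @export
molecules_per_cell <- function(fraction, total_per_cell = 1e7, round_thousand = FALSE) {
  if (any(fraction < 0) || any(fraction > 1)) {
    stop("molecules_per_cell: fraction must be in [0, 1]")
  }
  x <- fraction * total_per_cell
  if (round_thousand) x <- round(x / 1000) * 1000
  x
}
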