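#' Position-specific nucleotide frequencies of a pool
#'
#' Read-count-weighted base frequencies per piRNA position (T reported as U).
#' Positions beyond a record's length contribute nothing to that position's
#' denominator, so mixed-length pools are well defined (ragged
#' normalisation).
#'
#' @param pool a `pirna_pool` (or any data.frame with `sequence` and `count`).
#' @param weighted weight by read counts (`FALSE`: each unique sequence
#'   counts once).
#' @param max_pos number of positions reported (default: longest sequence).
#' @return position-frequency matrix `max_pos x 4` (columns A, C, G, U) with
#'   attribute `n_effective` (total weight at position 1).
#' @export
position_frequencies <- function(pool, weighted = TRUE, max_pos = NULL) {
  recs <- if (inherits(pool, "pirna_pool")) pool$records else pool
  if (nrow(recs) == 0L) stop("position_frequencies: empty pool")
  w <- if (weighted) recs$count else rep(1, nrow(recs))
  len <- nchar(recs$sequence)
  if (is.null(max_pos)) max_pos <- max(len)
  bases <- c("A", "C", "G", "T")
  m <- matrix(0, max_pos, 4L,
              dimnames = list(seq_len(max_pos), c("A", "C", "G", "U")))
  for (p in seq_len(max_pos)) {
    sel <- len >= p
    if (!any(sel)) next
    b <- substr(recs$sequence[sel], p, p)
    tot <- tapply(w[sel], factor(b, levels = bases), sum, default = 0)
    m[p, ] <- tot / sum(tot)
  }
  structure(m, n_effective = sum(w))
}

#' @rdname position_frequencies
#' @param pfm a position-frequency matrix.
#' @export
u1_fraction <- function(pfm) unname(pfm[1L, "U"])

#' @rdname position_frequencies
#' @export
a10_fraction <- function(pfm) unname(pfm[10L, "A"])

#' Ping-pong 5'-overlap profile
#'
#' For every pair of genomic hits on opposite strands of the same chromosome,
#' the 5'-end overlap length (plus-strand 5' at `p`, minus-strand 5' at `q`
#' overlap by `q - p + 1` nt) is accumulated with the product of the pair
#' weights. Slicer-driven ping-pong amplification concentrates mass at
#' offset 10; `z10` scores offset 10 against the other offsets.
#'
#' @param hits data.frame from [map_perfect()].
#' @param pool optional `pirna_pool`; when given, each hit is weighted by
#'   `read count x weight_share`, otherwise by `weight_share` alone.
#' @param offsets overlap offsets evaluated (nt).
#' @return object of class `pingpong_profile`: list with `offsets`, `weight`
#'   (co-occurrence weight per offset) and `z10`
#'   (`(w10 - mean(w_others)) / sd(w_others)`; `NA` when undefined).
#' @export
ping_pong_overlap <- function(hits, pool = NULL, offsets = 1:20) {
  dt <- data.table::as.data.table(hits)
  if (!is.null(pool)) {
    cnt <- pool$records$count[match(dt$sequence, pool$records$sequence)]
    dt[, weight := weight_share * cnt]
  } else {
    dt[, weight := weight_share]
  }
  w <- stats::setNames(numeric(length(offsets)), offsets)
  for (ch in unique(dt$chrom)) {
    sub <- dt[chrom == ch]
    plus <- sub[strand == "+", .(w = sum(weight)), by = five_prime]
    minus <- sub[strand == "-", .(w = sum(weight)), by = five_prime]
    if (nrow(plus) == 0L || nrow(minus) == 0L) next
    mw <- stats::setNames(minus$w, minus$five_prime)
    for (k in seq_along(offsets)) {
      q <- as.character(plus$five_prime + offsets[k] - 1L)
      hit <- q %in% names(mw)
      if (any(hit)) w[k] <- w[k] + sum(plus$w[hit] * mw[q[hit]])
    }
  }
  others <- w[offsets != 10L]
  z10 <- NA_real_
  if (10L %in% offsets && sum(w > 0) >= 2L && stats::sd(others) > 0) {
    z10 <- (w[offsets == 10L] - mean(others)) / stats::sd(others)
  }
  structure(list(offsets = offsets, weight = unname(w), z10 = unname(z10)),
            class = "pingpong_profile")
}

#' @export
print.pingpong_profile <- function(x, ...) {
  cat("Ping-pong 5'-overlap profile; z10 =",
      if (is.na(x$z10)) "undefined" else sprintf("%.2f", x$z10), "\n")
  invisible(x)
}
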