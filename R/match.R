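#' Matching rule parameters
#'
#' The evaluated guide window runs from `window_start` to `window_end` in
#' 1-based piRNA coordinates counted from the 5' end; up to `max_mismatches`
#' mismatches are tolerated inside the window. Position 1 and any 3' tail
#' beyond `window_end` are never evaluated. Defaults encode "<=1 mismatch
#' across nt 2-21". G:U wobble counts as a mismatch (ungapped Hamming rule).
#'
#' @param window_start,window_end window bounds (1-based, inclusive).
#' @param max_mismatches maximum tolerated mismatches within the window.
#' @return an object of class `match_params`.
#' @export
match_params <- function(window_start = 2L, window_end = 21L, max_mismatches = 1L) {
  stopifnot(window_start >= 1L, window_end >= window_start, max_mismatches >= 0L)
  structure(list(window_start = as.integer(window_start),
                 window_end = as.integer(window_end),
                 max_mismatches = as.integer(max_mismatches),
                 window_length = as.integer(window_end - window_start + 1L)),
            class = "match_params")
}

#' Antisense window of a piRNA
#'
#' Reverse complement of piRNA positions `window_start..window_end`; this
#' string is compared directly against the mRNA sense sequence.
#'
#' @param pirna piRNA sequence(s) as DNA strings (U written as T); vectorised.
#' @param params a [match_params()].
#' @return character vector of antisense windows.
#' @export
antisense_window <- function(pirna, params = match_params()) {
  pirna <- toupper(chartr("U", "T", pirna))
  if (any(nchar(pirna) < params$window_end)) {
    stop("antisense_window: piRNA shorter than window_end")
  }
  revcomp(substr(pirna, params$window_start, params$window_end))
}

# piRNA coordinate of a mismatch at window column j (1-based, left-to-right in
# transcript orientation): the antisense window is reversed, so column j pairs
# with piRNA position window_end - j + 1.
window_col_to_pirna_pos <- function(j, params) params$window_end - j + 1L

# transcript position paired with piRNA nt k for a site starting at s
site_pair_pos <- function(s, k, params) s + params$window_end - k

#' Brute-force site search for one piRNA on one transcript
#'
#' Reference implementation of the matching rule: slides the antisense window
#' over the transcript and reports every offset with Hamming distance at most
#' `max_mismatches`. Used as the oracle for the seed-indexed matcher.
#'
#' @param pirna one piRNA sequence.
#' @param transcript a `transcript_seq` or a plain DNA string.
#' @param params a [match_params()].
#' @return data.frame with one row per site: `start`, `end` (1-based closed
#'   transcript interval paired to the window), `mismatch_count`,
#'   `mismatch_positions` (comma-joined 1-based piRNA positions),
#'   `slice_pos` (transcript position paired to piRNA nt 10).
#' @export
find_sites_bruteforce <- function(pirna, transcript, params = match_params()) {
  seq <- if (inherits(transcript, "transcript_seq")) transcript$sequence else transcript
  w <- antisense_window(pirna, params)
  L <- params$window_length
  n <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatch_count = integer(0),
                      mismatch_positions = character(0), slice_pos = integer(0))
  if (n < L) return(empty)
  s_raw <- charToRaw(seq)
  w_raw <- charToRaw(w)
  raw_n <- charToRaw("N")
  n_off <- n - L + 1L
  mm <- integer(n_off)
  for (j in seq_len(L)) {
    sj <- s_raw[j:(n_off + j - 1L)]
    mm <- mm + as.integer(sj != w_raw[j] | sj == raw_n | w_raw[j] == raw_n)
  }
  hit <- which(mm <= params$max_mismatches)
  if (!length(hit)) return(empty)
  mp <- vapply(hit, function(o) {
    cols <- which(s_raw[o:(o + L - 1L)] != w_raw | s_raw[o:(o + L - 1L)] == raw_n |
                    w_raw == raw_n)
    paste(sort(window_col_to_pirna_pos(cols, params)), collapse = ",")
  }, character(1))
  data.frame(start = hit, end = hit + L - 1L, mismatch_count = mm[hit],
             mismatch_positions = mp,
             slice_pos = site_pair_pos(hit, 10L, params))
}

#' Build a pigeonhole seed index over a transcriptome
#'
#' The window is split into `max_mismatches + 1` near-equal seeds (the last
#' seed takes the remainder); by the pigeonhole principle every site within
#' the mismatch budget contains at least one exact seed, so exact seed lookup
#' plus verification recovers the brute-force site set.
#'
#' @param transcripts named list of `transcript_seq` (or named character
#'   vector of mRNA sequences).
#' @param params a [match_params()].
#' @return an object of class `seed_index`.
#' @export
build_seed_index <- function(transcripts, params = match_params()) {
  seqs <- if (is.character(transcripts)) transcripts else
    vapply(transcripts, function(t) t$sequence, character(1))
  gene_ids <- names(seqs)
  if (is.null(gene_ids)) stop("build_seed_index: transcripts must be named")
  k <- params$max_mismatches + 1L
  L <- params$window_length
  base <- L %/% k
  if (base == 0L) stop("build_seed_index: window shorter than seed count")
  seed_len <- rep(base, k)
  seed_len[k] <- L - base * (k - 1L)
  seed_off <- cumsum(c(1L, seed_len[-k]))
  tables <- list()
  for (l in unique(seed_len)) {
    per_tx <- lapply(seq_along(seqs), function(i) {
      n <- nchar(seqs[[i]])
      if (n < l) return(NULL)
      pos <- seq_len(n - l + 1L)
      data.table::data.table(kmer = substring(seqs[[i]], pos, pos + l - 1L),
                             tx = i, pos = pos)
    })
    dt <- data.table::rbindlist(per_tx)
    data.table::setkey(dt, kmer)
    tables[[as.character(l)]] <- dt
  }
  structure(list(params = params, gene_ids = gene_ids, tx_seqs = unname(seqs),
                 seed_len = seed_len, seed_off = seed_off, tables = tables),
            class = "seed_index")
}

#' Match a piRNA pool against an indexed transcriptome
#'
#' Finds every antisense target site of every pool sequence under the rule in
#' the index's [match_params()]. piRNAs shorter than `window_end` are skipped
#' and tallied in the `n_too_short` attribute.
#'
#' @param pool a `pirna_pool`.
#' @param index a `seed_index` from [build_seed_index()].
#' @return a site table: data.frame with columns `pirna`, `gene_id`, `start`,
#'   `end`, `mismatch_count`, `mismatch_positions`, `slice_pos`, `count`
#'   (read count of the piRNA). One row per distinct (piRNA, gene, start).
#' @export
match_pool <- function(pool, index) {
  params <- index$params
  recs <- pool$records
  ok <- nchar(recs$sequence) >= params$window_end
  n_short <- sum(!ok)
  recs <- recs[ok, , drop = FALSE]
  empty <- data.frame(pirna = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatch_count = integer(0),
                      mismatch_positions = character(0),
                      slice_pos = integer(0), count = integer(0))
  attr(empty, "n_too_short") <- n_short
  if (nrow(recs) == 0L) return(empty)
  windows <- antisense_window(recs$sequence, params)
  uw <- unique(windows)
  wid_of_rec <- match(windows, uw)
  L <- params$window_length
  # candidate generation: exact hits of each seed slot
  cand <- list()
  for (s in seq_along(index$seed_len)) {
    l <- index$seed_len[s]
    off <- index$seed_off[s]
    dt <- index$tables[[as.character(l)]]
    q <- data.table::data.table(kmer = substring(uw, off, off + l - 1L),
                                window_id = seq_along(uw))
    hits <- dt[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits)) {
      cand[[s]] <- data.table::data.table(window_id = hits$window_id,
                                          tx = hits$tx,
                                          start = hits$pos - off + 1L)
    }
  }
  cand <- data.table::rbindlist(cand)
  if (nrow(cand) == 0L) return(empty)
  cand <- unique(cand)
  cand <- cand[cand$start >= 1L & cand$start + L - 1L <= nchar(index$tx_seqs)[cand$tx], ]
  if (nrow(cand) == 0L) return(empty)
  ver <- verify_candidates_cpp(uw[cand$window_id], index$tx_seqs,
                               cand$tx, cand$start, params$max_mismatches)
  keep <- ver[, 1] <= params$max_mismatches
  cand <- cand[keep, ]
  ver <- ver[keep, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  mp <- apply(ver, 1, function(r) {
    cols <- r[-1]
    cols <- cols[cols > 0L]
    paste(sort(window_col_to_pirna_pos(cols, params)), collapse = ",")
  })
  sites <- data.table::data.table(window_id = cand$window_id,
                                  gene_id = index$gene_ids[cand$tx],
                                  start = cand$start,
                                  mismatch_count = ver[, 1],
                                  mismatch_positions = mp)
  # expand windows back to the individual piRNA records sharing them
  rec_map <- data.table::data.table(window_id = wid_of_rec,
                                    pirna = recs$sequence, count = recs$count)
  out <- merge(sites, rec_map, by = "window_id", allow.cartesian = TRUE)
  out[, `:=`(end = start + L - 1L,
             slice_pos = site_pair_pos(start, 10L, params))]
  data.table::setorder(out, gene_id, start, pirna)
  out <- as.data.frame(out[, .(pirna, gene_id, start, end, mismatch_count,
                               mismatch_positions, slice_pos, count)])
  attr(out, "n_too_short") <- n_short
  out
}

#' Brute-force pool matching (oracle)
#'
#' Same output contract as [match_pool()] but computed by exhaustive sliding
#' of every piRNA over every transcript. Quadratic; for tests and small inputs.
#'
#' @inheritParams match_pool
#' @param transcripts named list of `transcript_seq` or named character vector.
#' @param params a [match_params()].
#' @export
match_pool_bruteforce <- function(pool, transcripts, params = match_params()) {
  seqs <- if (is.character(transcripts)) transcripts else
    vapply(transcripts, function(t) t$sequence, character(1))
  rows <- list()
  for (i in seq_len(nrow(pool$records))) {
    p <- pool$records$sequence[i]
    if (nchar(p) < params$window_end) next
    for (g in names(seqs)) {
      st <- find_sites_bruteforce(p, seqs[[g]], params)
      if (nrow(st)) {
        st$pirna <- p
        st$gene_id <- g
        st$count <- pool$records$count[i]
        rows[[length(rows) + 1L]] <- st
      }
    }
  }
  if (!length(rows)) {
    out <- data.frame(pirna = character(0), gene_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatch_count = integer(0),
                      mismatch_positions = character(0),
                      slice_pos = integer(0), count = integer(0))
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$start, out$pirna),
             c("pirna", "gene_id", "start", "end", "mismatch_count",
               "mismatch_positions", "slice_pos", "count")]
  rownames(out) <- NULL
  out
}
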