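#' Alignment scoring scheme
#'
#' Affine-gap local alignment scores: a gap of length `k` costs
#' `gap_open + k * gap_ext`.
#'
#' @param match,mismatch,gap_open,gap_ext scoring parameters (penalties
#'   positive).
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2) {
  list(match = match, mismatch = mismatch, gap_open = gap_open, gap_ext = gap_ext)
}

# run one Smith-Waterman pass; returns NULL below min_score
sw_one <- function(a, b, scoring, min_score) {
  r <- sw_align_cpp(a, b, scoring$match, scoring$mismatch,
                    scoring$gap_open, scoring$gap_ext)
  if (r$score < min_score || is.na(r$a_start)) return(NULL)
  r
}

#' Local alignment with suboptimal, query-disjoint hits
#'
#' Smith-Waterman (affine gaps) of `a` against `b`. Both orientations of `a`
#' are tried; after recording the best local alignment the query is split at
#' the aligned interval and both remainders are re-aligned, so reported
#' alignments are non-overlapping on `a`. Alignments below `min_score` are
#' discarded.
#'
#' @param a,b DNA strings (query and subject).
#' @param scoring an [align_scoring()] list.
#' @param min_score minimum reported alignment score.
#' @return list of alignments, each a list with `score`, `query_interval`
#'   (1-based closed on forward `a`), `subject_interval`, `strand_relation`
#'   (`"sense"`/`"antisense"`), `percent_identity`, `n_columns`, `n_matches`
#'   and `columns` (two-column matrix of aligned `a`/`b` positions, 0 marking
#'   a gap). Sorted by decreasing score.
#' @export
local_align <- function(a, b, scoring = align_scoring(), min_score = 40) {
  if (!nzchar(a) || !nzchar(b)) stop("local_align: empty sequence")
  a <- toupper(a)
  b <- toupper(b)
  out <- list()
  recurse <- function(lo, hi) {
    if (hi - lo + 1L < 10L) return()
    seg <- substr(a, lo, hi)
    cand <- list()
    fs <- sw_one(seg, b, scoring, min_score)
    if (!is.null(fs)) cand[["sense"]] <- fs
    rs <- sw_one(revcomp(seg), b, scoring, min_score)
    if (!is.null(rs)) cand[["antisense"]] <- rs
    if (!length(cand)) return()
    ori <- names(cand)[which.max(vapply(cand, `[[`, numeric(1), "score"))]
    r <- cand[[ori]]
    seg_len <- hi - lo + 1L
    if (ori == "sense") {
      q0 <- lo + r$a_start - 1L
      q1 <- lo + r$a_end - 1L
      qpos <- ifelse(r$a_pos > 0L, lo + r$a_pos - 1L, 0L)
    } else {
      # positions in revcomp(seg) map back to forward coordinates
      q0 <- lo + (seg_len - r$a_end)
      q1 <- lo + (seg_len - r$a_start)
      qpos <- ifelse(r$a_pos > 0L, lo + (seg_len - r$a_pos), 0L)
    }
    cols <- cbind(q = qpos, s = r$b_pos)
    aligned <- cols[, 1] > 0L & cols[, 2] > 0L
    qa <- substring(a, cols[aligned, 1], cols[aligned, 1])
    if (ori == "antisense") qa <- revcomp(qa)
    sa <- substring(b, cols[aligned, 2], cols[aligned, 2])
    n_match <- sum(qa == sa & qa != "N")
    out[[length(out) + 1L]] <<- list(
      score = r$score,
      query_interval = c(q0, q1),
      subject_interval = c(r$b_start, r$b_end),
      strand_relation = ori,
      percent_identity = 100 * n_match / nrow(cols),
      n_columns = nrow(cols),
      n_matches = n_match,
      columns = cols)
    recurse(lo, q0 - 1L)
    recurse(q1 + 1L, hi)
  }
  recurse(1L, nchar(a))
  out[order(-vapply(out, `[[`, numeric(1), "score"))]
}

# chain query-sorted alignments that are collinear on the subject for their
# orientation; subject adjacency tolerance subj_tol
chain_alignments <- function(alns, subj_tol = 10L) {
  if (!length(alns)) return(list())
  q0 <- vapply(alns, function(x) x$query_interval[1], numeric(1))
  alns <- alns[order(q0)]
  chains <- list()
  cur <- list(alns[[1]])
  for (i in seq_along(alns)[-1]) {
    prev <- cur[[length(cur)]]
    nxt <- alns[[i]]
    same_ori <- identical(prev$strand_relation, nxt$strand_relation)
    link <- FALSE
    if (same_ori) {
      sg <- if (nxt$strand_relation == "sense") {
        nxt$subject_interval[1] - prev$subject_interval[2] - 1L
      } else {
        prev$subject_interval[1] - nxt$subject_interval[2] - 1L
      }
      link <- sg >= -subj_tol
    }
    if (link) cur[[length(cur) + 1L]] <- nxt
    else { chains[[length(chains) + 1L]] <- cur; cur <- list(nxt) }
  }
  chains[[length(chains) + 1L]] <- cur
  chains
}

# mRNA-sense sequence of the intron between mRNA-order exons k and k+1
intron_sequence <- function(gene, genome, k) {
  ex <- gene$exons
  n_ex <- nrow(ex)
  if (gene$strand == "+") {
    i <- k # genomic order == mRNA order
    if (i >= n_ex) return(NULL)
    s <- substr(genome[[gene$chrom]], ex$end[i] + 1L, ex$start[i + 1L] - 1L)
    s
  } else {
    i <- n_ex - k # mRNA exon k is genomic exon n_ex - k + 1
    if (i < 1L) return(NULL)
    s <- substr(genome[[gene$chrom]], ex$end[i] + 1L, ex$start[i + 1L] - 1L)
    revcomp(s)
  }
}

#' Scan a cluster sequence for pseudogene fragments
#'
#' Local-aligns the cluster sequence against each transcript, chains
#' collinear alignment segments, and reports fragments passing the length and
#' identity thresholds with their anatomy: exon composition, 5' truncation
#' (alignment starts more than `trunc_threshold` nt into the mRNA) and
#' processed state. A chain whose query-side insertion between
#' subject-adjacent segments aligns to the corresponding annotated intron at
#' more than 80% identity is called `partly_processed`, otherwise
#' `processed`.
#'
#' @param cluster_seq cluster DNA string.
#' @param transcripts named list of `transcript_seq`.
#' @param gene_models named list of `gene_model` (for intron lookup).
#' @param genome named character vector (needed for the intron test; `NULL`
#'   skips it).
#' @param cluster_id label for the output.
#' @param cluster_offset genomic coordinate of cluster position 1 minus 1
#'   (for genomic intervals in the output).
#' @param min_len minimum aligned columns of a fragment.
#' @param min_identity minimum percent identity.
#' @param min_score per-segment score threshold passed to [local_align()].
#' @param trunc_threshold nt of mRNA 5' end that may be missing before the
#'   fragment is called truncated.
#' @param min_exon_cov minimum aligned nt within an exon for it to be listed
#'   in `exons_covered`.
#' @param scoring an [align_scoring()] list.
#' @return data.frame with one row per fragment: `cluster_id`, `gene_id`,
#'   `q_start`, `q_end` (cluster coords), `g_start`, `g_end` (genomic),
#'   `s_start`, `s_end` (transcript), `strand_relation`, `percent_identity`,
#'   `n_segments`, `exons_covered` (comma string), `five_prime_truncated`,
#'   `processed_state`, `retained_introns` (comma string).
#' @export
scan_pgf <- function(cluster_seq, transcripts, gene_models = NULL, genome = NULL,
                     cluster_id = "cluster", cluster_offset = 0L,
                     min_len = 100L, min_identity = 80, min_score = 40,
                     trunc_threshold = 50L, min_exon_cov = 10L,
                     scoring = align_scoring()) {
  hits <- list()
  for (g in names(transcripts)) {
    tx <- transcripts[[g]]
    alns <- local_align(cluster_seq, tx$sequence, scoring, min_score)
    if (!length(alns)) next
    for (chain in chain_alignments(alns)) {
      n_cols <- sum(vapply(chain, `[[`, numeric(1), "n_columns"))
      n_match <- sum(vapply(chain, `[[`, numeric(1), "n_matches"))
      pid <- 100 * n_match / n_cols
      if (n_cols < min_len || pid < min_identity) next
      q_rng <- range(unlist(lapply(chain, `[[`, "query_interval")))
      s_rng <- range(unlist(lapply(chain, `[[`, "subject_interval")))
      s_pos <- unlist(lapply(chain, function(x) x$columns[x$columns[, 2] > 0L, 2]))
      # an exon counts as covered with >= min_exon_cov aligned nt, so chance
      # extension of a local alignment past the fragment edge is not reported
      ex_tab <- table(tx$exon_index[s_pos])
      exons <- sort(as.integer(names(ex_tab)[ex_tab >= min_exon_cov]))
      state <- "processed"
      introns <- integer(0)
      if (length(chain) > 1L && !is.null(genome) && !is.null(gene_models)) {
        gm <- gene_models[[g]]
        for (i in seq_along(chain)[-1]) {
          prev <- chain[[i - 1L]]
          nxt <- chain[[i]]
          qg0 <- prev$query_interval[2] + 1L
          qg1 <- nxt$query_interval[1] - 1L
          if (qg1 - qg0 + 1L < 30L) next
          gap_seq <- substr(cluster_seq, qg0, qg1)
          if (prev$strand_relation == "antisense") gap_seq <- revcomp(gap_seq)
          # transcript coordinates flanking the junction; alignment ends may
          # spill a few chance-matching bases across it, so the exon ordinal
          # is read a little inside each segment and both candidates tried
          if (prev$strand_relation == "sense") {
            s_low_end <- prev$subject_interval[2]
            s_high_start <- nxt$subject_interval[1]
          } else {
            s_low_end <- nxt$subject_interval[2]
            s_high_start <- prev$subject_interval[1]
          }
          cand_k <- unique(c(tx$exon_index[max(1L, s_low_end - 5L)],
                             tx$exon_index[min(tx$length, s_high_start + 5L)] - 1L))
          for (k in cand_k) {
            if (k < 1L) next
            iseq <- intron_sequence(gm, genome, k)
            if (is.null(iseq) || nchar(iseq) < 20L) next
            ia <- local_align(gap_seq, iseq, scoring, min_score)
            if (length(ia) && ia[[1]]$percent_identity > 80 &&
                ia[[1]]$n_columns >= 0.5 * nchar(iseq)) {
              state <- "partly_processed"
              introns <- c(introns, k)
              break
            }
          }
        }
      }
      hits[[length(hits) + 1L]] <- data.frame(
        cluster_id = cluster_id, gene_id = g,
        q_start = q_rng[1], q_end = q_rng[2],
        g_start = cluster_offset + q_rng[1], g_end = cluster_offset + q_rng[2],
        s_start = s_rng[1], s_end = s_rng[2],
        strand_relation = chain[[1]]$strand_relation,
        percent_identity = pid, n_segments = length(chain),
        exons_covered = paste(exons, collapse = ","),
        five_prime_truncated = s_rng[1] > trunc_threshold,
        processed_state = state,
        retained_introns = paste(introns, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(cluster_id = character(0), gene_id = character(0),
                      q_start = integer(0), q_end = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      strand_relation = character(0),
                      percent_identity = numeric(0), n_segments = integer(0),
                      exons_covered = character(0),
                      five_prime_truncated = logical(0),
                      processed_state = character(0),
                      retained_introns = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(-out$percent_identity * (out$q_end - out$q_start + 1)), , drop = FALSE]
}

#' Detect a target-site duplication flanking an insertion
#'
#' Finds the longest exact direct repeat with one copy ending within
#' `boundary_slack` nt of the insertion 5' boundary and the other beginning
#' within `boundary_slack` nt of the 3' boundary. The returned repeat is
#' maximal: it cannot be extended by one base on either end and remain exact
#' in both copies.
#'
#' @param chrom_seq chromosome sequence containing the insertion.
#' @param pgf_start,pgf_end 1-based closed insertion interval.
#' @param search_window nt of flank searched on each side.
#' @param min_len minimum repeat length reported.
#' @param boundary_slack allowed distance between a copy and its boundary.
#' @return `NULL` if no repeat of at least `min_len` is found, else a list
#'   with `repeat_length`, `left_copy` and `right_copy` (1-based closed
#'   intervals), `sequence` and `offset_slack_used`.
#' @export
detect_tsd <- function(chrom_seq, pgf_start, pgf_end, search_window = 30L,
                       min_len = 8L, boundary_slack = 5L) {
  n <- nchar(chrom_seq)
  if (pgf_start - search_window - boundary_slack < 1L ||
      pgf_end + search_window + boundary_slack > n) {
    stop("detect_tsd: insufficient flanking sequence")
  }
  left_b <- pgf_start - 1L  # expected end of the left copy
  right_b <- pgf_end + 1L   # expected start of the right copy
  max_k <- search_window
  best <- NULL
  g <- function(i, j) substr(chrom_seq, i, j)
  for (j in (right_b - boundary_slack):(right_b + boundary_slack)) {
    for (i in (left_b - boundary_slack - max_k + 1L):(left_b + boundary_slack)) {
      # maximal forward run from (i, j)
      k <- 0L
      while (k < max_k &&
             substr(chrom_seq, i + k, i + k) == substr(chrom_seq, j + k, j + k)) {
        k <- k + 1L
      }
      if (k < min_len) next
      # maximality: not left-extendable (right-extendability ended the run)
      if (i > 1L && j > 1L &&
          substr(chrom_seq, i - 1L, i - 1L) == substr(chrom_seq, j - 1L, j - 1L)) next
      left_end <- i + k - 1L
      if (abs(left_end - left_b) > boundary_slack) next
      if (abs(j - right_b) > boundary_slack) next
      slack <- max(abs(left_end - left_b), abs(j - right_b))
      cand <- list(repeat_length = k, left_copy = c(i, left_end),
                   right_copy = c(j, j + k - 1L), sequence = g(i, left_end),
                   offset_slack_used = slack)
      if (is.null(best) || k > best$repeat_length ||
          (k == best$repeat_length && slack < best$offset_slack_used)) {
        best <- cand
      }
    }
  }
  best
}

#' Pairwise identity between two loci
#'
#' Chains query-disjoint local alignments (greedily resolving subject
#' overlaps by score) and reports identity as matches over aligned columns
#' across all retained segments, for ribbon-style locus comparisons.
#'
#' @param locus_a,locus_b DNA strings.
#' @param scoring an [align_scoring()] list.
#' @param min_score segment score threshold.
#' @return list with `comparable` (any segment retained), `identity`
#'   (percent, `NA` when not comparable), `n_columns`, and `segments`
#'   (data.frame of per-segment intervals and identities).
#' @export
pairwise_identity <- function(locus_a, locus_b, scoring = align_scoring(),
                              min_score = 40) {
  if (!nzchar(locus_a) || !nzchar(locus_b)) stop("pairwise_identity: empty locus")
  alns <- local_align(locus_a, locus_b, scoring, min_score)
  keep <- list()
  taken <- logical(nchar(locus_b))
  for (al in alns) { # already sorted by decreasing score
    s <- al$subject_interval
    if (mean(taken[s[1]:s[2]]) > 0.25) next
    taken[s[1]:s[2]] <- TRUE
    keep[[length(keep) + 1L]] <- al
  }
  if (!length(keep)) {
    return(list(comparable = FALSE, identity = NA_real_, n_columns = 0L,
                segments = data.frame()))
  }
  seg <- do.call(rbind, lapply(keep, function(x) {
    data.frame(a_start = x$query_interval[1], a_end = x$query_interval[2],
               b_start = x$subject_interval[1], b_end = x$subject_interval[2],
               strand_relation = x$strand_relation, score = x$score,
               percent_identity = x$percent_identity,
               n_columns = x$n_columns, n_matches = x$n_matches)
  }))
  list(comparable = TRUE,
       identity = 100 * sum(seg$n_matches) / sum(seg$n_columns),
       n_columns = sum(seg$n_columns), segments = seg)
}
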