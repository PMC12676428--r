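# piRNA pool sampling from a simulated genome bundle.

# Valid 5'-start positions for targeting reads of length l emitted from a
# pseudogene fragment on cluster strand st. A start is valid when the read
# lies inside the cluster, the guide window falls inside an exonic block of
# the fragment and contains at most max_mismatches divergence mutations, and
# (for diverged fragments) the read is distinguishable from the parent gene:
# it covers a mutated position or a spliced exon-exon junction.
valid_pgf_starts <- function(pgf, l, st, params, cl_start, cl_end) {
  ws <- params$window_start
  we <- params$window_end
  mm <- params$max_mismatches
  mut <- sort(pgf$mutations)
  jn <- sort(pgf$junctions)
  out <- integer(0)
  for (bi in seq_len(nrow(pgf$exon_blocks))) {
    bs <- pgf$exon_blocks[bi, 1]
    be <- pgf$exon_blocks[bi, 2]
    if (st == "+") {
      lo <- max(cl_start, bs - ws + 1L)
      hi <- min(cl_end - l + 1L, be - we + 1L)
    } else {
      lo <- max(cl_start, bs - l + we)
      hi <- min(cl_end - l + 1L, be - l + ws)
    }
    if (lo > hi) next
    s <- lo:hi
    win_lo <- if (st == "+") s + ws - 1L else s + l - we
    win_hi <- if (st == "+") s + we - 1L else s + l - ws
    if (length(mut)) {
      n_in_win <- findInterval(win_hi, mut) - findInterval(win_lo - 1L, mut)
      s <- s[n_in_win <= mm]
      if (!length(s)) next
    }
    if (pgf$divergence > 0) {
      in_read_mut <- findInterval(s + l - 1L, mut) - findInterval(s - 1L, mut)
      in_read_jn <- if (length(jn)) {
        findInterval(s + l - 2L, jn) - findInterval(s - 1L, jn)
      } else rep(0L, length(s))
      s <- s[in_read_mut + in_read_jn >= 1L]
    }
    out <- c(out, s)
  }
  sort(unique(out))
}

# cluster-body starts: read inside the cluster, not overlapping any fragment
valid_body_starts <- function(cl_start, cl_end, pgfs, l) {
  if (cl_end - l + 1L < cl_start) return(integer(0))
  s <- cl_start:(cl_end - l + 1L)
  for (p in pgfs) {
    s <- s[s > p$end | s + l - 1L < p$start]
  }
  s
}

# draw n starts from T-starting / non-T-starting candidate sets according to
# the 1U probability; falls back (with a warning) when one set is empty
draw_starts <- function(t_set, nt_set, n, u1) {
  if (n == 0L) return(integer(0))
  if (!length(t_set) && !length(nt_set)) return(integer(0))
  if (!length(t_set)) {
    if (u1 > 0) warning("1U bias unmet: no T-starting positions available")
    return(sample_with_replacement(nt_set, n))
  }
  if (!length(nt_set)) return(sample_with_replacement(t_set, n))
  n_t <- stats::rbinom(1L, n, u1)
  c(sample_with_replacement(t_set, n_t), sample_with_replacement(nt_set, n - n_t))
}

sample_with_replacement <- function(x, n) {
  if (n == 0L) return(integer(0))
  x[sample.int(length(x), n, replace = TRUE)]
}

#' Sample a piRNA read pool from a simulated genome
#'
#' Reads are genome substrings (strand-aware), so perfect genomic mapping is
#' lossless. Primary reads are apportioned between intergenic background and
#' clusters by the configured weights; within a fragment-bearing cluster a
#' `pgf_fraction` of reads starts at valid targeting positions of its
#' fragments (see the methods vignette for the validity rule) and the rest is
#' uniform over the non-fragment cluster body. The 1U bias is implemented by
#' start-site choice: with probability `u1_probability` the start is drawn
#' from T-starting positions, else from non-T-starting ones. When
#' `pingpong_fraction > 0`, that fraction of reads is emitted as
#' opposite-strand responders whose 5' ends overlap a partner read by 10 nt.
#'
#' @param bundle a `sim_bundle` from [simulate_genome_and_annotation()].
#' @param seed optional seed (default: continue the current RNG stream).
#' @param params the [match_params()] defining targeting validity.
#' @return list with `reads` (character vector) and `truth` (data.frame:
#'   `read_id`, `sequence`, `chrom`, `start`, `end`, `strand`, `source`
#'   (cluster id, `BACKGROUND`, or `MATE`), `pgf_id`).
#' @export
sample_pirnas <- function(bundle, seed = NULL, params = match_params()) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- bundle$config
  ps <- cfg$pirna_sampling
  chrom <- names(bundle$genome)[1]
  chrom_seq <- bundle$genome[[1]]
  raw <- charToRaw(chrom_seq)
  is_t <- raw == charToRaw("T")
  is_a <- raw == charToRaw("A")
  lens <- as.integer(names(ps$length_probs))
  lp <- as.numeric(ps$length_probs)
  u1 <- ps$u1_probability
  N <- ps$total_reads
  n_pp <- round(ps$pingpong_fraction * N)
  n_primary <- N - n_pp
  cl <- bundle$clusters
  cw <- ps$cluster_weights %||% numeric(0)
  probs <- c(ps$background_fraction,
             (1 - ps$background_fraction) * cw[cl$cluster_id])
  counts <- as.vector(stats::rmultinom(1L, n_primary, probs))
  n_bg <- counts[1]
  n_cl <- stats::setNames(counts[-1], cl$cluster_id)
  pgfs_by_cluster <- split(bundle$pgf_truth,
                           vapply(bundle$pgf_truth, `[[`, character(1), "cluster_id"))

  rows <- list()
  emit <- function(starts, l, st, source, pgf_id) {
    if (!length(starts)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      start = starts, end = starts + l - 1L, strand = st,
      source = source, pgf_id = pgf_id, stringsAsFactors = FALSE)
  }
  split_t <- function(s, st, l) {
    tt <- if (st == "+") is_t[s] else is_a[s + l - 1L]
    list(t = s[tt], nt = s[!tt])
  }

  # background from intergenic spacers
  if (n_bg > 0L) {
    for (st in c("+", "-")) {
      n_st <- if (st == "+") ceiling(n_bg / 2) else floor(n_bg / 2)
      lc <- as.vector(stats::rmultinom(1L, n_st, lp))
      for (k in seq_along(lens)) {
        if (lc[k] == 0L) next
        l <- lens[k]
        spc <- bundle$spacers
        ok <- spc[, 2] - spc[, 1] + 1L >= l
        s_all <- unlist(Map(function(a, b) a:(b - l + 1L),
                            spc[ok, 1], spc[ok, 2]), use.names = FALSE)
        sets <- split_t(s_all, st, l)
        emit(draw_starts(sets$t, sets$nt, lc[k], u1), l, st, "BACKGROUND", NA_character_)
      }
    }
  }

  # cluster reads
  for (i in seq_len(nrow(cl))) {
    cid <- cl$cluster_id[i]
    n_c <- n_cl[cid]
    if (is.na(n_c) || n_c == 0L) next
    st <- cl$strand[i]
    if (!st %in% c("+", "-")) st <- "+"
    pg <- pgfs_by_cluster[[cid]] %||% list()
    n_pgf <- if (length(pg)) stats::rbinom(1L, n_c, ps$pgf_fraction) else 0L
    n_body <- n_c - n_pgf
    if (n_pgf > 0L) {
      per_pgf <- as.vector(stats::rmultinom(1L, n_pgf, rep(1, length(pg))))
      for (j in seq_along(pg)) {
        lc <- as.vector(stats::rmultinom(1L, per_pgf[j], lp))
        for (k in seq_along(lens)) {
          if (lc[k] == 0L) next
          l <- lens[k]
          v <- valid_pgf_starts(pg[[j]], l, st, params, cl$start[i], cl$end[i])
          sets <- split_t(v, st, l)
          emit(draw_starts(sets$t, sets$nt, lc[k], u1), l, st, cid,
               pg[[j]]$pgf_id)
        }
      }
    }
    if (n_body > 0L) {
      lc <- as.vector(stats::rmultinom(1L, n_body, lp))
      for (k in seq_along(lens)) {
        if (lc[k] == 0L) next
        l <- lens[k]
        v <- valid_body_starts(cl$start[i], cl$end[i], pg, l)
        sets <- split_t(v, st, l)
        emit(draw_starts(sets$t, sets$nt, lc[k], u1), l, st, cid, NA_character_)
      }
    }
  }

  truth <- data.table::rbindlist(rows)

  # ping-pong responder mates: opposite strand, 5' ends overlapping by 10 nt
  if (n_pp > 0L && nrow(truth) > 0L) {
    partners <- truth[sample.int(nrow(truth), n_pp, replace = TRUE)]
    l <- lens[sample.int(length(lens), n_pp, replace = TRUE, prob = lp)]
    p5 <- ifelse(partners$strand == "+", partners$start, partners$end)
    mate_st <- ifelse(partners$strand == "+", "-", "+")
    mstart <- ifelse(mate_st == "-", p5 + 9L - l + 1L, p5 - 9L)
    mend <- mstart + l - 1L
    okb <- mstart >= 1L & mend <= nchar(chrom_seq)
    mates <- data.frame(start = mstart[okb], end = mend[okb],
                        strand = mate_st[okb], source = "MATE",
                        pgf_id = NA_character_, stringsAsFactors = FALSE)
    truth <- data.table::rbindlist(list(truth, mates))
  }

  truth <- as.data.frame(truth)
  seqs <- substring(chrom_seq, truth$start, truth$end)
  minus <- truth$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  truth <- data.frame(read_id = sprintf("r%07d", seq_len(nrow(truth))),
                      sequence = seqs, chrom = chrom, truth,
                      stringsAsFactors = FALSE)
  list(reads = seqs, truth = truth)
}

#' Simulate a complete dataset (genome, annotation, reads)
#'
#' Runs [simulate_genome_and_annotation()] followed by [sample_pirnas()]
#' under a single RNG stream, so the whole bundle is deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()] (or config name / path / list).
#' @return a `sim_bundle` with `reads` and `read_truth` filled in.
#' @export
simulate_dataset <- function(config) {
  bundle <- simulate_genome_and_annotation(config)
  rr <- sample_pirnas(bundle)
  bundle$reads <- rr$reads
  bundle$read_truth <- rr$truth
  bundle
}

#' Simulate a gene-level expression table with planted target upregulation
#'
#' Top targets are drawn from `Normal(effect_size_top, sd)`, lower targets
#' from `Normal(effect_size_lower, sd)` and non-targets from `Normal(0, sd)`
#' on the log2 fold-change scale. `padj` is a Benjamini-Hochberg-adjusted
#' one-sample z p-value against 0 (a placeholder consistent with consuming a
#' differential-expression table; the package never estimates expression
#' itself).
#'
#' @param top_genes,lower_genes character vectors of target gene ids.
#' @param config a [sim_config()] (its `expression` block is used).
#' @param seed optional seed.
#' @return data.frame `gene_id`, `log2fc`, `padj`, plus a `groups` attribute
#'   with the planted group of every gene.
#' @export
simulate_expression <- function(top_genes, lower_genes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ex <- config$expression
  non <- sprintf("nt%04d", seq_len(ex$n_non_targets))
  gene_id <- c(top_genes, lower_genes, non)
  mu <- c(rep(ex$effect_size_top, length(top_genes)),
          rep(ex$effect_size_lower, length(lower_genes)),
          rep(0, length(non)))
  log2fc <- stats::rnorm(length(gene_id), mu, ex$sd)
  p <- 2 * stats::pnorm(-abs(log2fc) / ex$sd)
  out <- data.frame(gene_id = gene_id, log2fc = log2fc,
                    padj = stats::p.adjust(p, "BH"))
  attr(out, "groups") <- rep(c("top", "lower", "non"),
                             c(length(top_genes), length(lower_genes), length(non)))
  out
}

#' Write a truth bundle to disk
#'
#' Emits `genome.fa`, `genes.gtf`, `clusters.bed`, `pgf_truth.bed`,
#' `pgf_anatomy.tsv`, `reads.fa` and `read_truth.tsv`, validating on write
#' that every read is a strand-aware genome substring and every planted
#' target-site duplication is an exact direct repeat.
#'
#' @param bundle a `sim_bundle` with reads.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$genome, file.path(dir, "genome.fa"))
  write_gtf(bundle$models, file.path(dir, "genes.gtf"))
  write_bed6(bundle$clusters, file.path(dir, "clusters.bed"))
  chrom_seq <- bundle$genome[[1]]
  pt <- lapply(bundle$pgf_truth, function(p) {
    left <- substr(chrom_seq, p$tsd_left[1], p$tsd_left[2])
    right <- substr(chrom_seq, p$end + 1L, p$end + p$tsd_length)
    if (!identical(left, right)) {
      stop("truth validation failed: TSD copies differ for ", p$pgf_id)
    }
    data.frame(pgf_id = p$pgf_id, cluster_id = p$cluster_id, chrom = p$chrom,
               start = p$start, end = p$end, source_gene = p$source_gene,
               exon_from = p$exon_range[1], exon_to = p$exon_range[2],
               truncation = p$truncation, divergence = p$divergence,
               tsd_length = p$tsd_length, orientation = p$orientation,
               include_intron = p$include_intron, stringsAsFactors = FALSE)
  })
  pt <- do.call(rbind, pt)
  write_tsv_table(pt, file.path(dir, "pgf_anatomy.tsv"))
  write_bed6(data.frame(cluster_id = pt$pgf_id, chrom = pt$chrom,
                        start = pt$start, end = pt$end, score = 0L,
                        strand = ifelse(pt$orientation == "antisense", "-", "+")),
             file.path(dir, "pgf_truth.bed"))
  if (!is.null(bundle$read_truth)) {
    tr <- bundle$read_truth
    chk <- substring(chrom_seq, tr$start, tr$end)
    minus <- tr$strand == "-"
    chk[minus] <- revcomp(chk[minus])
    if (!identical(chk, tr$sequence)) {
      stop("truth validation failed: read not a genome substring")
    }
    reads <- stats::setNames(tr$sequence, tr$read_id)
    write_fasta(reads, file.path(dir, "reads.fa"))
    write_tsv_table(tr, file.path(dir, "read_truth.tsv"))
  }
  invisible(dir)
}
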