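# Synthetic-data generator: genomes with planted genes, piRNA clusters,
# pseudogene-fragment insertions and read pools with full ground truth.

# Build one gene piece: random sequence with an internal exon/intron layout.
# Coordinates are relative to the piece (1-based).
build_gene_piece <- function(spec, gc) {
  n_ex <- spec$n_exons
  ex_len <- if (spec$exon_len[1] == spec$exon_len[2]) rep(spec$exon_len[1], n_ex)
            else sample(spec$exon_len[1]:spec$exon_len[2], n_ex, replace = TRUE)
  in_len <- if (n_ex == 1L) integer(0)
            else if (spec$intron_len[1] == spec$intron_len[2])
              rep(spec$intron_len[1], n_ex - 1L)
            else sample(spec$intron_len[1]:spec$intron_len[2], n_ex - 1L,
                        replace = TRUE)
  total <- sum(ex_len) + sum(in_len)
  seq <- random_dna(total, gc)
  starts <- cumsum(c(1L, utils::head(ex_len + c(in_len, 0L), -1L)))
  exons <- data.frame(start = starts, end = starts + ex_len - 1L)
  n_spliced <- sum(ex_len)
  utr5 <- spec$utr5_len
  utr3 <- spec$utr3_len
  if (utr5 + utr3 >= n_spliced) stop("gene spec: UTRs exceed spliced length")
  # CDS occupies spliced positions (utr5+1)..(n_spliced-utr3); project to
  # genomic coordinates respecting strand
  g_pos <- unlist(Map(seq.int, exons$start, exons$end), use.names = FALSE)
  if (spec$strand == "-") g_pos <- rev(g_pos)
  cds_span <- range(g_pos[(utr5 + 1L):(n_spliced - utr3)])
  list(gene_id = spec$gene_id, seq = seq, length = total, exons = exons,
       cds_span = cds_span, strand = spec$strand)
}

#' Insert a pseudogene fragment into a cluster sequence
#'
#' Splices the configured exon range of the source transcript (optionally
#' retaining the intron before the last exon of the range, giving a partly
#' processed fragment), truncates the 5' end, applies point divergence,
#' orients the fragment, and inserts it at a random interior position with an
#' exact target-site duplication of `tsd_length` nt flanking both ends. The
#' insertion point is resampled until the duplication is not extendable by
#' flank coincidence, so the planted TSD length is exactly recoverable.
#'
#' @param cluster_seq host cluster sequence.
#' @param tx source `transcript_seq` (piece-relative coordinates are fine).
#' @param gene source `gene_model`-like list with `exons` and `strand`.
#' @param gene_seq the gene's own sequence (for retained introns).
#' @param spec PGF spec list: `exon_range`, `five_prime_truncation`,
#'   `divergence`, `tsd_length`, `orientation`, `include_intron`.
#' @param margin minimum distance of the insertion from the cluster ends.
#' @return list with `seq` (modified cluster sequence) and `truth`
#'   (cluster-relative fragment anatomy: `start`, `end`, `tsd_length`,
#'   `orientation`, mutated positions, exonic blocks, spliced-junction
#'   positions, retained-intron block).
#' @export
insert_pgf <- function(cluster_seq, tx, gene, gene_seq, spec, margin = 60L) {
  e1 <- spec$exon_range[1]
  e2 <- spec$exon_range[2]
  pos <- which(tx$exon_index >= e1 & tx$exon_index <= e2)
  if (!length(pos)) stop("insert_pgf: exon range outside transcript")
  stopifnot(all(diff(pos) == 1L))
  # mRNA-sense fragment, with per-base block labels:
  # exon ordinal for exonic bases, 0 for retained intron
  if (isTRUE(spec$include_intron) && e2 > e1) {
    head_pos <- pos[tx$exon_index[pos] < e2]
    tail_pos <- pos[tx$exon_index[pos] == e2]
    intron <- intron_sequence(list(exons = gene$exons, strand = gene$strand,
                                   chrom = "piece"),
                              stats::setNames(list(gene_seq), "piece"), e2 - 1L)
    frag <- paste0(substr(tx$sequence, min(head_pos), max(head_pos)), intron,
                   substr(tx$sequence, min(tail_pos), max(tail_pos)))
    labels <- c(tx$exon_index[head_pos], rep(0L, nchar(intron)),
                tx$exon_index[tail_pos])
  } else {
    frag <- substr(tx$sequence, min(pos), max(pos))
    labels <- tx$exon_index[pos]
  }
  trunc <- spec$five_prime_truncation
  if (trunc > 0L) {
    frag <- substr(frag, trunc + 1L, nchar(frag))
    labels <- labels[-seq_len(trunc)]
  }
  L <- nchar(frag)
  # point divergence: substitutions at Bernoulli positions
  div <- spec$divergence %||% 0
  mut <- integer(0)
  if (div > 0) {
    mut <- which(stats::runif(L) < div)
    if (length(mut)) {
      ch <- strsplit(frag, "")[[1]]
      ch[mut] <- vapply(ch[mut], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                        character(1))
      frag <- paste(ch, collapse = "")
    }
  }
  antisense <- identical(spec$orientation, "antisense")
  g_frag <- if (antisense) revcomp(frag) else frag
  g_labels <- if (antisense) rev(labels) else labels
  g_mut <- if (antisense) sort(L - mut + 1L) else mut
  # spliced exon-exon junctions (boundaries between adjacent exonic bases of
  # different ordinals): positions b such that bases b and b+1 flank a splice
  jn <- which(g_labels[-L] != g_labels[-1L] & g_labels[-L] > 0L & g_labels[-1L] > 0L)
  t_len <- spec$tsd_length
  n <- nchar(cluster_seq)
  if (n < 2L * margin + t_len + 10L) stop("insert_pgf: host cluster too small")
  first_b <- substr(g_frag, 1L, 1L)
  last_b <- substr(g_frag, L, L)
  p <- NA_integer_
  for (try in 1:200) {
    cand <- sample((margin):(n - margin - t_len), 1L)
    # non-extendable duplication: base before left copy differs from the
    # fragment's last base; base after right copy differs from its first base
    if (substr(cluster_seq, cand, cand) != last_b &&
        substr(cluster_seq, cand + t_len + 1L, cand + t_len + 1L) != first_b) {
      p <- cand
      break
    }
  }
  if (is.na(p)) stop("insert_pgf: could not place a non-extendable TSD")
  new_seq <- paste0(substr(cluster_seq, 1L, p + t_len), g_frag,
                    substr(cluster_seq, p + 1L, n))
  pgf_start <- p + t_len + 1L
  # contiguous blocks of exonic bases (cluster-relative)
  r <- rle(g_labels > 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ex_blocks <- cbind(start = pgf_start + starts[r$values] - 1L,
                     end = pgf_start + ends[r$values] - 1L)
  intron_block <- if (any(!r$values)) {
    cbind(start = pgf_start + starts[!r$values] - 1L,
          end = pgf_start + ends[!r$values] - 1L)
  } else NULL
  list(seq = new_seq,
       truth = list(start = pgf_start, end = pgf_start + L - 1L,
                    tsd_length = t_len, orientation = spec$orientation,
                    tsd_left = c(p + 1L, p + t_len),
                    mutations = pgf_start + g_mut - 1L,
                    exon_blocks = ex_blocks, intron_block = intron_block,
                    junctions = pgf_start + jn - 1L,
                    exon_range = c(e1, e2), divergence = div,
                    truncation = trunc,
                    include_intron = isTRUE(spec$include_intron)))
}

#' Simulate a genome with genes, clusters and pseudogene insertions
#'
#' Lays out gene and cluster pieces in random order separated by random
#' intergenic spacers, inserts the configured pseudogene fragments into
#' their host clusters, and returns the assembled genome with all
#' annotations and fragment ground truth. Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list (class `sim_bundle`) with `genome`, `models`, `transcripts`,
#'   `clusters` (annotation data.frame), `pgf_truth` (named list of
#'   fragment anatomies, absolute coordinates), `spacers` (intergenic
#'   intervals), `config`.
#' @export
simulate_genome_and_annotation <- function(config) {
  config <- if (inherits(config, "sim_config")) config else sim_config(config)
  set.seed(config$seed)
  gc <- config$genome$gc_content
  chrom <- config$genome$chrom
  gene_pieces <- lapply(config$genes, build_gene_piece, gc = gc)
  names(gene_pieces) <- vapply(gene_pieces, `[[`, character(1), "gene_id")
  # relative transcripts for fragment construction
  rel_tx <- lapply(gene_pieces, function(gp) {
    gm <- gene_model(gp$gene_id, "piece", gp$strand, gp$exons, gp$cds_span)
    build_transcript(gm, stats::setNames(c(gp$seq), "piece"))
  })
  cluster_pieces <- list()
  for (cl in config$clusters) {
    cluster_pieces[[cl$cluster_id]] <-
      list(cluster_id = cl$cluster_id, strand = cl$strand,
           seq = random_dna(cl$length, gc), pgfs = list())
  }
  for (spec in config$pgfs) {
    host <- cluster_pieces[[spec$host_cluster]]
    if (is.null(host)) stop("unknown host cluster ", spec$host_cluster)
    gp <- gene_pieces[[spec$source_gene]]
    ins <- insert_pgf(host$seq, rel_tx[[spec$source_gene]],
                      list(exons = gp$exons, strand = gp$strand),
                      gp$seq, spec)
    host$seq <- ins$seq
    ins$truth$pgf_id <- spec$pgf_id %||% paste0("pgf_", spec$source_gene)
    ins$truth$source_gene <- spec$source_gene
    host$pgfs[[length(host$pgfs) + 1L]] <- ins$truth
    cluster_pieces[[spec$host_cluster]] <- host
  }
  pieces <- c(lapply(gene_pieces, function(g) list(type = "gene", id = g$gene_id,
                                                  seq = g$seq)),
              lapply(cluster_pieces, function(cl) list(type = "cluster",
                                                       id = cl$cluster_id,
                                                       seq = cl$seq)))
  pieces <- pieces[sample(length(pieces))]
  n_pieces <- length(pieces)
  total_piece <- sum(vapply(pieces, function(p) nchar(p$seq), numeric(1)))
  n_spacer <- n_pieces + 1L
  spare <- config$genome$length - total_piece - 100L * n_spacer
  if (spare < 0L) {
    stop("simulate_genome_and_annotation: requested features exceed genome ",
         "capacity; increase genome length by at least ", -spare, " nt")
  }
  extra <- if (spare > 0L) as.vector(stats::rmultinom(1L, spare, rep(1, n_spacer))) else
    rep(0L, n_spacer)
  spacer_len <- 100L + extra
  # assemble and record absolute offsets
  seq_parts <- character(0)
  offsets <- integer(n_pieces)
  spacers <- matrix(0L, n_spacer, 2L)
  at <- 0L
  for (i in seq_len(n_pieces)) {
    seq_parts <- c(seq_parts, random_dna(spacer_len[i], gc))
    spacers[i, ] <- c(at + 1L, at + spacer_len[i])
    at <- at + spacer_len[i]
    offsets[i] <- at
    seq_parts <- c(seq_parts, pieces[[i]]$seq)
    at <- at + nchar(pieces[[i]]$seq)
  }
  seq_parts <- c(seq_parts, random_dna(spacer_len[n_spacer], gc))
  spacers[n_spacer, ] <- c(at + 1L, at + spacer_len[n_spacer])
  genome <- stats::setNames(paste(seq_parts, collapse = ""), chrom)
  # absolute annotations
  models <- list()
  clusters <- list()
  pgf_truth <- list()
  for (i in seq_len(n_pieces)) {
    pc <- pieces[[i]]
    off <- offsets[i]
    if (pc$type == "gene") {
      gp <- gene_pieces[[pc$id]]
      models[[pc$id]] <- gene_model(pc$id, chrom, gp$strand,
                                    gp$exons + off, gp$cds_span + off)
    } else {
      cl <- cluster_pieces[[pc$id]]
      clusters[[length(clusters) + 1L]] <-
        data.frame(cluster_id = pc$id, chrom = chrom, start = off + 1L,
                   end = off + nchar(cl$seq), score = 0L, strand = cl$strand,
                   stringsAsFactors = FALSE)
      for (tr in cl$pgfs) {
        for (f in c("start", "end", "mutations", "junctions", "tsd_left")) {
          tr[[f]] <- tr[[f]] + off
        }
        if (!is.null(tr$exon_blocks)) tr$exon_blocks <- tr$exon_blocks + off
        if (!is.null(tr$intron_block)) tr$intron_block <- tr$intron_block + off
        tr$cluster_id <- pc$id
        tr$chrom <- chrom
        pgf_truth[[tr$pgf_id]] <- tr
      }
    }
  }
  clusters <- do.call(rbind, clusters)
  clusters <- clusters[order(clusters$start), ]
  rownames(clusters) <- NULL
  transcripts <- build_transcriptome(models, genome)
  structure(list(genome = genome, models = models, transcripts = transcripts,
                 clusters = clusters, pgf_truth = pgf_truth,
                 spacers = spacers, config = config),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d nt genome, %d genes, %d clusters, %d PGFs%s\n",
              nchar(x$genome[[1]]), length(x$models), nrow(x$clusters),
              length(x$pgf_truth),
              if (is.null(x$reads)) "" else sprintf(", %d reads", length(x$reads))))
  invisible(x)
}
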