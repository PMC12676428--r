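#' Map pool sequences perfectly to the genome
#'
#' Exact full-length occurrences on both strands ([Biostrings::matchPDict()]
#' per read length). A sequence with `k` occurrences receives weight share
#' `1/k` at each. Sequences with zero occurrences are reported in the
#' `unmapped` attribute.
#'
#' @param pool a `pirna_pool`.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame of genomic hits: `sequence`, `chrom`, `start`, `end`
#'   (1-based closed, leftmost-based), `strand`, `five_prime` (strand-aware
#'   genomic coordinate of the read 5' end), `n_hits`, `weight_share`.
#' @export
map_perfect <- function(pool, genome) {
  seqs <- pool$records$sequence
  hits <- list()
  for (len in sort(unique(nchar(seqs)))) {
    sub <- seqs[nchar(seqs) == len]
    pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(sub))
    pd_rev <- Biostrings::PDict(Biostrings::reverseComplement(Biostrings::DNAStringSet(sub)))
    for (chrom in names(genome)) {
      subject <- Biostrings::DNAString(genome[[chrom]])
      for (sense in c("+", "-")) {
        pd <- if (sense == "+") pd_fwd else pd_rev
        mi <- Biostrings::matchPDict(pd, subject)
        cnt <- S4Vectors::elementNROWS(mi)
        if (sum(cnt) == 0L) next
        starts <- unlist(IRanges::start(mi), use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.table::data.table(
          sequence = rep(sub, cnt),
          chrom = chrom,
          start = starts,
          end = starts + len - 1L,
          strand = sense)
      }
    }
  }
  if (!length(hits)) {
    out <- data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), five_prime = integer(0),
                      n_hits = integer(0), weight_share = numeric(0))
    attr(out, "unmapped") <- seqs
    return(out)
  }
  dt <- data.table::rbindlist(hits)
  dt[, five_prime := data.table::fifelse(strand == "+", start, end)]
  dt[, n_hits := .N, by = sequence]
  dt[, weight_share := 1 / n_hits]
  data.table::setorder(dt, sequence, chrom, start, strand)
  out <- as.data.frame(dt)
  attr(out, "unmapped") <- setdiff(seqs, dt$sequence)
  out
}

#' Attribute genomic hits to source clusters
#'
#' A hit belongs to the cluster containing its strand-aware 5'-end
#' coordinate, else to `NON_PIC`. Cluster annotations must be
#' non-overlapping.
#'
#' @param hits data.frame from [map_perfect()].
#' @param clusters cluster annotation data.frame (`cluster_id`, `chrom`,
#'   `start`, `end`, 1-based closed) as from [read_bed6()].
#' @return data.frame of per-piRNA source weights: `sequence`,
#'   `source_label`, `share` (shares of one sequence sum to 1).
#' @export
attribute_sources <- function(hits, clusters) {
  for (ch in unique(clusters$chrom)) {
    cc <- clusters[clusters$chrom == ch, ]
    cc <- cc[order(cc$start), ]
    if (nrow(cc) > 1 && any(cc$start[-1] <= cc$end[-nrow(cc)])) {
      stop("attribute_sources: overlapping cluster annotations on ", ch)
    }
  }
  dt <- data.table::as.data.table(hits)
  dt[, source_label := "NON_PIC"]
  for (i in seq_len(nrow(clusters))) {
    sel <- dt$chrom == clusters$chrom[i] & dt$five_prime >= clusters$start[i] &
      dt$five_prime <= clusters$end[i]
    dt[sel, source_label := clusters$cluster_id[i]]
  }
  out <- dt[, .(share = sum(weight_share)), by = .(sequence, source_label)]
  data.table::setorder(out, sequence, -share, source_label)
  as.data.frame(out)
}

#' Decompose a gene's targeting piRNA weight by source locus
#'
#' The gene's targeting weight (under the chosen multi-target policy) is
#' partitioned across source labels via each piRNA's genomic weight shares.
#' Targeting piRNAs without a perfect genomic hit appear under `UNMAPPED`
#' and are excluded from fractions unless `include_unmapped = TRUE`.
#'
#' @param gene_id gene to decompose.
#' @param site_table site table from [match_pool()].
#' @param source_weights data.frame from [attribute_sources()].
#' @param policy multi-target weight policy, see [aggregate_by_gene()].
#' @param include_unmapped keep `UNMAPPED` weight in the fractions.
#' @return object of class `cluster_decomposition`: `gene_id`, `entries`
#'   (data.frame `source_label`, `weight`, `fraction`, sorted descending) and
#'   `summary` (named vector `top`, `second`, `third`, `minor_lt5`,
#'   `non_pic`; clusters contributing `< 5%` each are pooled as `minor_lt5`).
#' @export
decompose_gene <- function(gene_id, site_table, source_weights,
                           policy = c("split", "full"), include_unmapped = FALSE) {
  policy <- match.arg(policy)
  gid <- gene_id
  if (!gid %in% site_table$gene_id) stop("decompose_gene: gene not in site table")
  dt <- data.table::as.data.table(site_table)
  pg <- unique(dt[, .(pirna, gene_id, count)])
  pg[, n_genes := .N, by = pirna]
  pg <- pg[gene_id == gid]
  pg[, weight := if (policy == "split") count / n_genes else as.numeric(count)]
  sw <- data.table::as.data.table(source_weights)
  m <- merge(pg[, .(pirna, weight)], sw, by.x = "pirna", by.y = "sequence",
             all.x = TRUE)
  m[is.na(source_label), `:=`(source_label = "UNMAPPED", share = 1)]
  ent <- m[, .(weight = sum(weight * share)), by = source_label]
  if (!include_unmapped) ent <- ent[source_label != "UNMAPPED"]
  if (nrow(ent) == 0L) stop("decompose_gene: no attributable weight")
  ent[, fraction := weight / sum(weight)]
  data.table::setorder(ent, -fraction, source_label)
  entries <- as.data.frame(ent)
  pic <- entries[!entries$source_label %in% c("NON_PIC", "UNMAPPED"), ]
  non_pic <- sum(entries$fraction[entries$source_label == "NON_PIC"])
  minor <- sum(pic$fraction[pic$fraction < 0.05])
  major <- pic$fraction[pic$fraction >= 0.05]
  # a >=5% cluster past the third slot is folded into minor_lt5 (degenerate
  # at desk scale; keeps the five summary fields an exact partition)
  if (length(major) > 3L) {
    minor <- minor + sum(major[-(1:3)])
    major <- major[1:3]
  }
  summary <- c(top = if (length(major) >= 1) major[1] else 0,
               second = if (length(major) >= 2) major[2] else 0,
               third = if (length(major) >= 3) major[3] else 0,
               minor_lt5 = minor, non_pic = non_pic)
  structure(list(gene_id = gid, entries = entries, summary = summary,
                 policy = policy), class = "cluster_decomposition")
}

#' @export
print.cluster_decomposition <- function(x, ...) {
  cat(sprintf("Decomposition of targeting weight for %s (%s policy)\n",
              x$gene_id, x$policy))
  print(round(x$summary, 4))
  invisible(x)
}

#' Classify targeting piRNAs as cis or trans
#'
#' A (piRNA, gene) pair is `cis` when some perfect genomic hit of the piRNA
#' overlaps the target gene's exon union, else `trans`.
#'
#' @param site_table site table from [match_pool()].
#' @param hits data.frame from [map_perfect()].
#' @param gene_models named list of `gene_model` objects.
#' @return data.frame `pirna`, `gene_id`, `label`, `count`, with attribute
#'   `trans_fraction` (read-weighted fraction of trans pairs).
#' @export
classify_cis_trans <- function(site_table, hits, gene_models) {
  dt <- data.table::as.data.table(site_table)
  pairs <- unique(dt[, .(pirna, gene_id, count)])
  ex <- data.table::as.data.table(exon_table(gene_models))
  h <- data.table::as.data.table(hits)[, .(pirna = sequence, chrom, start, end)]
  ph <- merge(pairs[, .(pirna, gene_id)], h, by = "pirna",
              allow.cartesian = TRUE)
  ph <- merge(ph, ex[, .(gene_id, chrom, ex_start = start, ex_end = end)],
              by = c("gene_id", "chrom"), allow.cartesian = TRUE)
  cis_pairs <- unique(ph[start <= ex_end & end >= ex_start, .(pirna, gene_id)])
  out <- as.data.frame(pairs)
  is_cis <- paste(out$pirna, out$gene_id) %in%
    paste(cis_pairs$pirna, cis_pairs$gene_id)
  out$label <- ifelse(is_cis, "cis", "trans")
  attr(out, "trans_fraction") <- sum(out$count[out$label == "trans"]) / sum(out$count)
  out
}
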