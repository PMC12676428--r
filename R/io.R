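#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (names are the full
#'   header lines without the leading `>`).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' Write sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @export
write_fasta <- function(x, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(x)
  names(ss) <- names(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (qualities discarded)
#'
#' @param path FASTQ file.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Read / write tab-separated tables
#'
#' Plain TSV with a header row; used for all tabular outputs.
#'
#' @param path file path.
#' @return `read_tsv_table`: a data.frame.
#' @export
read_tsv_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- BED6 (0-based half-open on file, 1-based closed in memory) -------------

#' Read a BED6 cluster annotation
#'
#' File intervals are 0-based half-open; in-memory intervals are 1-based
#' closed. Strand `.` denotes a bidirectional cluster.
#'
#' @param path BED6 file.
#' @return data.frame with columns `cluster_id`, `chrom`, `start`, `end`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad)) {
    stop(sprintf("BED6 parse error at line %d of %s: expected 6 fields, got %d",
                 bad[1], path, lengths(parts)[bad[1]]))
  }
  m <- do.call(rbind, parts)
  start0 <- suppressWarnings(as.integer(m[, 2]))
  end0 <- suppressWarnings(as.integer(m[, 3]))
  if (anyNA(start0) || anyNA(end0)) {
    stop(sprintf("BED6 parse error at line %d of %s: non-integer coordinates",
                 which(is.na(start0) | is.na(end0))[1], path))
  }
  if (any(end0 <= start0)) stop("BED6: empty interval")
  score <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(score)) score <- m[, 5]
  data.frame(cluster_id = m[, 4], chrom = m[, 1], start = start0 + 1L,
             end = end0, score = score, strand = m[, 6],
             stringsAsFactors = FALSE)
}

#' @rdname read_bed6
#' @param clusters data.frame as returned by [read_bed6()].
#' @export
write_bed6 <- function(clusters, path) {
  score <- if ("score" %in% names(clusters)) clusters$score else rep(0L, nrow(clusters))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", clusters$chrom,
                   clusters$start - 1L, clusters$end, clusters$cluster_id,
                   as.character(score), clusters$strand)
  writeLines(lines, path)
  invisible(path)
}

# ---- gene models -------------------------------------------------------------

#' Construct a gene model
#'
#' Exons are 1-based closed genomic intervals on `chrom`; they must be sorted
#' and pairwise disjoint. `cds_span` is a genomic interval `c(start, end)`
#' contained in the exon union, or `NULL` for a non-coding model.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of exon `start`, `end`.
#' @param cds_span length-2 integer vector or `NULL`.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_span = NULL) {
  exons <- as.data.frame(exons)
  names(exons)[1:2] <- c("start", "end")
  exons <- exons[order(exons$start), , drop = FALSE]
  stopifnot(strand %in% c("+", "-"), all(exons$end >= exons$start))
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    stop("gene_model: exons must be pairwise disjoint")
  }
  if (!is.null(cds_span)) {
    stopifnot(length(cds_span) == 2, cds_span[2] >= cds_span[1])
    cov <- sum(pmax(0L, pmin(exons$end, cds_span[2]) - pmax(exons$start, cds_span[1]) + 1L))
    if (cov == 0L) stop("gene_model: cds_span outside exon union")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_span = cds_span),
            class = "gene_model")
}

#' Genomic exon union of a set of gene models
#'
#' @param models list of `gene_model` objects.
#' @return data.frame with one row per exon (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @export
exon_table <- function(models) {
  do.call(rbind, lapply(models, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$exons$start, end = g$exons$end,
               stringsAsFactors = FALSE)
  }))
}

#' Write gene models as GTF
#'
#' One `exon` row per exon and one `CDS` row per exon-overlapping piece of the
#' CDS span. GTF coordinates are 1-based closed, identical to the in-memory
#' convention.
#'
#' @param models list of `gene_model` objects.
#' @param path output GTF.
#' @param source value for the GTF source column.
#' @export
write_gtf <- function(models, path, source = "piswarm") {
  rows <- character(0)
  for (g in models) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g$gene_id, g$gene_id)
    rows <- c(rows, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, source, g$exons$start, g$exons$end,
                            g$strand, attr_str))
    if (!is.null(g$cds_span)) {
      cs <- pmax(g$exons$start, g$cds_span[1])
      ce <- pmin(g$exons$end, g$cds_span[2])
      keep <- ce >= cs
      rows <- c(rows, sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                              g$chrom, source, cs[keep], ce[keep], g$strand, attr_str))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Exons of all transcripts of a gene are collapsed to their genomic union;
#' CDS labels are taken from the union span of all CDS records, so one model
#' per gene results regardless of annotated isoforms.
#'
#' @param path GTF file.
#' @return named list of `gene_model` objects.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  typ <- as.character(gr$type)
  gid <- gr$gene_id
  out <- list()
  for (g in unique(gid)) {
    sel <- gid == g & typ == "exon"
    if (!any(sel)) next
    ex <- IRanges::reduce(IRanges::IRanges(GenomicRanges::start(gr[sel]),
                                           GenomicRanges::end(gr[sel])))
    cds_sel <- gid == g & typ == "CDS"
    cds_span <- NULL
    if (any(cds_sel)) {
      cds_span <- c(min(GenomicRanges::start(gr[cds_sel])),
                    max(GenomicRanges::end(gr[cds_sel])))
    }
    out[[g]] <- gene_model(
      gene_id = g,
      chrom = as.character(GenomicRanges::seqnames(gr[sel]))[1],
      strand = as.character(GenomicRanges::strand(gr[sel]))[1],
      exons = data.frame(start = IRanges::start(ex), end = IRanges::end(ex)),
      cds_span = cds_span)
  }
  out
}

# ---- transcript construction -------------------------------------------------

#' Build the spliced transcript of a gene
#'
#' Exon substrings are concatenated in genomic order and reverse-complemented
#' as a whole for minus-strand genes, so the result reads 5'->3' in mRNA
#' sense. Feature labels (5UTR/CDS/3UTR) are derived by projecting the CDS
#' span; models without a CDS are retained for matching but flagged
#' (`has_cds = FALSE`) and carry no feature labels.
#'
#' @param gene a `gene_model`.
#' @param genome named character vector of chromosome sequences.
#' @return an object of class `transcript_seq` with elements `gene_id`,
#'   `sequence`, `length`, `has_cds`, `utr5_len`/`cds_len`/`utr3_len`,
#'   `exon_index` (per-position exon ordinal in mRNA order), `g_pos`
#'   (per-position genomic coordinate), `chrom`, `strand`.
#' @export
build_transcript <- function(gene, genome) {
  chrom_seq <- genome[[gene$chrom]]
  if (is.null(chrom_seq)) stop("build_transcript: unknown chromosome ", gene$chrom)
  glen <- nchar(chrom_seq)
  if (any(gene$exons$start < 1L) || any(gene$exons$end > glen)) {
    stop("build_transcript: exon outside genome bounds for ", gene$gene_id)
  }
  pieces <- substring(chrom_seq, gene$exons$start, gene$exons$end)
  seq_plus <- paste(pieces, collapse = "")
  widths <- gene$exons$end - gene$exons$start + 1L
  g_pos <- unlist(Map(seq.int, gene$exons$start, gene$exons$end), use.names = FALSE)
  ex_idx <- rep(seq_len(nrow(gene$exons)), widths)
  if (gene$strand == "-") {
    sequence <- revcomp(seq_plus)
    g_pos <- rev(g_pos)
    # exon ordinals count from the mRNA 5' end (genomically last exon first)
    ex_idx <- rep(seq_len(nrow(gene$exons)), rev(widths))
  } else {
    sequence <- seq_plus
  }
  n <- nchar(sequence)
  utr5 <- cds <- utr3 <- NA_integer_
  if (!is.null(gene$cds_span)) {
    in_cds <- g_pos >= gene$cds_span[1] & g_pos <= gene$cds_span[2]
    cds_pos <- which(in_cds)
    cds <- length(cds_pos)
    utr5 <- min(cds_pos) - 1L
    utr3 <- n - max(cds_pos)
  }
  structure(list(gene_id = gene$gene_id, sequence = sequence, length = n,
                 has_cds = !is.null(gene$cds_span),
                 utr5_len = utr5, cds_len = cds, utr3_len = utr3,
                 exon_index = ex_idx, g_pos = g_pos,
                 chrom = gene$chrom, strand = gene$strand),
            class = "transcript_seq")
}

#' Per-position feature labels of a transcript
#'
#' @param tx a `transcript_seq`.
#' @return character vector over `{"5UTR","CDS","3UTR"}` (or `NA` throughout
#'   for models without a CDS).
#' @export
feature_map <- function(tx) {
  if (!tx$has_cds) return(rep(NA_character_, tx$length))
  rep(c("5UTR", "CDS", "3UTR"), c(tx$utr5_len, tx$cds_len, tx$utr3_len))
}

#' Project transcript positions to the genome
#'
#' @param tx a `transcript_seq`.
#' @param pos integer vector of 1-based transcript positions.
#' @return data.frame with `chrom`, `g_pos`, `strand`.
#' @export
tx_to_genome <- function(tx, pos) {
  stopifnot(all(pos >= 1L), all(pos <= tx$length))
  data.frame(chrom = tx$chrom, g_pos = tx$g_pos[pos], strand = tx$strand,
             stringsAsFactors = FALSE)
}

#' Build the transcriptome of a gene-model set
#'
#' @param models named list of `gene_model` objects.
#' @param genome named character vector of chromosome sequences.
#' @return named list of `transcript_seq` objects.
#' @export
build_transcriptome <- function(models, genome) {
  out <- lapply(models, build_transcript, genome = genome)
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

# ---- piRNA pool --------------------------------------------------------------

#' Collapse raw reads into a weighted piRNA pool
#'
#' Identical sequences are merged with their occurrence count. Reads that
#' contain N or fall outside the length bounds are dropped and tallied.
#'
#' @param reads character vector of read sequences (FASTQ qualities ignored).
#' @param min_len,max_len retained length bounds in nt.
#' @return an object of class `pirna_pool`: `records` (data.frame `sequence`,
#'   `count`, sorted by decreasing count then sequence), `total_reads`,
#'   `dropped` (named counts of excluded reads).
#' @export
collapse_reads <- function(reads, min_len = 18L, max_len = 40L) {
  reads <- toupper(reads)
  has_n <- grepl("N", reads, fixed = TRUE)
  len <- nchar(reads)
  bad_len <- !has_n & (len < min_len | len > max_len)
  keep <- !has_n & !bad_len
  dropped <- c(with_n = sum(has_n), length = sum(bad_len))
  if (!any(keep)) {
    records <- data.frame(sequence = character(0), count = integer(0))
  } else {
    dt <- data.table::data.table(sequence = reads[keep])
    rec <- dt[, .(count = .N), by = sequence]
    data.table::setorder(rec, -count, sequence)
    records <- as.data.frame(rec)
  }
  structure(list(records = records, total_reads = sum(records$count),
                 dropped = dropped, min_len = min_len, max_len = max_len),
            class = "pirna_pool")
}

#' @export
print.pirna_pool <- function(x, ...) {
  cat(sprintf("piRNA pool: %d unique sequences, %d reads (dropped: %d with N, %d by length)\n",
              nrow(x$records), x$total_reads, x$dropped["with_n"], x$dropped["length"]))
  invisible(x)
}

#' Read / write a collapsed pool as FASTA with `count=` headers
#'
#' Headers have the form `>pi000001 count=12`.
#'
#' @param path FASTA file.
#' @return `read_pool_fasta`: a `pirna_pool`.
#' @export
read_pool_fasta <- function(path) {
  x <- read_fasta(path)
  counts <- suppressWarnings(as.integer(sub(".*count=(\\d+).*", "\\1", names(x))))
  if (anyNA(counts)) stop("read_pool_fasta: missing count= in header")
  records <- data.frame(sequence = unname(x), count = counts)
  rec <- data.table::as.data.table(records)[, .(count = sum(count)), by = sequence]
  data.table::setorder(rec, -count, sequence)
  structure(list(records = as.data.frame(rec), total_reads = sum(counts),
                 dropped = c(with_n = 0L, length = 0L),
                 min_len = min(nchar(x)), max_len = max(nchar(x))),
            class = "pirna_pool")
}

#' @rdname read_pool_fasta
#' @param pool a `pirna_pool`.
#' @export
write_pool_fasta <- function(pool, path) {
  x <- pool$records$sequence
  names(x) <- sprintf("pi%06d count=%d", seq_along(x), pool$records$count)
  write_fasta(x, path)
}
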