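# shared fixture builders; everything is generated in code at test time

make_pool <- function(seqs, counts = rep(1L, length(seqs))) {
  collapse_reads(rep(seqs, counts))
}

# independent oracle for perfect genomic mapping: compare every window of the
# genome (both strands) against every sequence by string equality
naive_genome_hits <- function(seqs, genome) {
  out <- list()
  for (chrom in names(genome)) {
    g <- genome[[chrom]]
    n <- nchar(g)
    for (s in seqs) {
      l <- nchar(s)
      if (l > n) next
      pos <- seq_len(n - l + 1L)
      win <- substring(g, pos, pos + l - 1L)
      for (p in pos[win == s]) {
        out[[length(out) + 1L]] <- data.frame(sequence = s, chrom = chrom,
                                              start = p, strand = "+")
      }
      rc <- revcomp(s)
      for (p in pos[win == rc]) {
        out[[length(out) + 1L]] <- data.frame(sequence = s, chrom = chrom,
                                              start = p, strand = "-")
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), chrom = character(0),
                      start = integer(0), strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$sequence, df$chrom, df$start, df$strand), ]
}

# a small three-feature plus-strand gene on a random genome
toy_transcriptome <- function(seed = 1) {
  set.seed(seed)
  genome <- c(chr1 = random_dna(3000))
  g1 <- gene_model("g1", "chr1", "+",
                   data.frame(start = c(101, 601, 1101),
                              end = c(400, 900, 1400)),
                   cds_span = c(201, 1200))
  g2 <- gene_model("g2", "chr1", "-",
                   data.frame(start = c(1601, 2101),
                              end = c(1900, 2400)),
                   cds_span = c(1701, 2300))
  models <- list(g1 = g1, g2 = g2)
  list(genome = genome, models = models,
       transcripts = build_transcriptome(models, genome))
}

# embed the antisense window of a piRNA into a transcript with n_mm mismatches
embed_window <- function(transcript, pirna, at, n_mm = 0L,
                         params = match_params()) {
  w <- antisense_window(pirna, params)
  if (n_mm > 0L) {
    idx <- sample(nchar(w), n_mm)
    ch <- strsplit(w, "")[[1]]
    for (i in idx) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    w <- paste(ch, collapse = "")
  }
  paste0(substr(transcript, 1, at - 1L), w,
         substr(transcript, at + nchar(w), nchar(transcript)))
}
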