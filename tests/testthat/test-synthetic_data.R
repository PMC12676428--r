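test_that("simulation is deterministic under the seed", {
  cfg <- sim_config("minimal")
  cfg$pirna_sampling$total_reads <- 1000L
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$reads, b2$reads)
  expect_identical(b1$clusters, b2$clusters)
  b3 <- simulate_dataset(sim_config("minimal", seed = 999))
  expect_false(identical(b1$genome, b3$genome))
})

test_that("base composition follows the configured GC content", {
  set.seed(77)
  s <- random_dna(1e5, gc = 0.5)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  # within 3 sd of Binomial(1e5, 0.5)
  expect_lt(abs(gc - 5e4), 3 * sqrt(1e5 * 0.25))
})

test_that("over-full genomes raise a placement error", {
  cfg <- sim_config("minimal")
  cfg$genome$length <- 3000L
  expect_error(simulate_genome_and_annotation(cfg), "capacity")
})

test_that("insert_pgf builds the configured anatomy exactly", {
  set.seed(83)
  fix <- toy_transcriptome(83)
  gp <- list(exons = fix$models$g1$exons, strand = "+")
  gene_seq <- substr(fix$genome[[1]], 1, 1500)
  # relative-coordinate transcript for the piece
  rel_model <- gene_model("g1", "piece", "+", fix$models$g1$exons,
                          fix$models$g1$cds_span)
  tx <- build_transcript(rel_model, c(piece = fix$genome[[1]]))
  cluster <- random_dna(1200)
  spec <- list(exon_range = c(2, 3), five_prime_truncation = 0,
               divergence = 0, tsd_length = 14, orientation = "antisense",
               include_intron = FALSE)
  ins <- insert_pgf(cluster, tx, gp, gene_seq, spec)
  tr <- ins$truth
  # inserted segment's revcomp equals the spliced exon 2-3 sequence exactly
  pos <- which(tx$exon_index %in% 2:3)
  expect_equal(revcomp(substr(ins$seq, tr$start, tr$end)),
               substr(tx$sequence, min(pos), max(pos)))
  # flanks share an exact 14-mer
  left <- substr(ins$seq, tr$start - 14, tr$start - 1)
  right <- substr(ins$seq, tr$end + 1, tr$end + 14)
  expect_identical(left, right)
  expect_equal(nchar(left), 14L)
  # divergence: ~5% of bases differ and identity lands near 95%
  spec$divergence <- 0.05
  ins2 <- insert_pgf(cluster, tx, gp, gene_seq, spec)
  tr2 <- ins2$truth
  frag <- revcomp(substr(ins2$seq, tr2$start, tr2$end))
  src <- substr(tx$sequence, min(pos), max(pos))
  mm <- sum(strsplit(frag, "")[[1]] != strsplit(src, "")[[1]])
  expect_equal(mm, length(tr2$mutations))
  expect_equal(mm / nchar(src), 0.05, tolerance = 0.5)
  # truncation removes the fragment 5' end
  spec$divergence <- 0
  spec$five_prime_truncation <- 50
  ins3 <- insert_pgf(cluster, tx, gp, gene_seq, spec)
  tr3 <- ins3$truth
  expect_equal(revcomp(substr(ins3$seq, tr3$start, tr3$end)),
               substr(tx$sequence, min(pos) + 50, max(pos)))
  # retained intron appears between the exon blocks
  spec$five_prime_truncation <- 0
  spec$include_intron <- TRUE
  ins4 <- insert_pgf(cluster, tx, gp, gene_seq, spec)
  tr4 <- ins4$truth
  expect_false(is.null(tr4$intron_block))
  intron <- substr(fix$genome[[1]], gp$exons$end[2] + 1, gp$exons$start[3] - 1)
  expect_equal(revcomp(substr(ins4$seq, tr4$intron_block[1], tr4$intron_block[2])),
               intron)
  expect_equal(nrow(tr4$exon_blocks), 2L)
})

test_that("all sampled reads are strand-aware genome substrings", {
  cfg <- sim_config("minimal")
  cfg$pirna_sampling$total_reads <- 2000L
  b <- simulate_dataset(cfg)
  tr <- b$read_truth
  chk <- substring(b$genome[[1]], tr$start, tr$end)
  minus <- tr$strand == "-"
  chk[minus] <- revcomp(chk[minus])
  expect_identical(chk, tr$sequence)
  expect_identical(b$reads, tr$sequence)
  # lengths follow the configured support
  expect_true(all(nchar(b$reads) %in% 26:32))
})

test_that("u1_probability 1 yields only T-starting reads", {
  cfg <- sim_config("minimal")
  cfg$pirna_sampling$total_reads <- 500L
  cfg$pirna_sampling$u1_probability <- 1
  b <- simulate_dataset(cfg)
  expect_true(all(substr(b$reads, 1, 1) == "T"))
})

test_that("the truth bundle round-trips through standard formats", {
  cfg <- sim_config("minimal")
  cfg$pirna_sampling$total_reads <- 500L
  b <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_truth_bundle(b, dir)
  genome2 <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(unname(genome2), unname(b$genome))
  models2 <- read_gtf(file.path(dir, "genes.gtf"))
  expect_setequal(names(models2), names(b$models))
  clusters2 <- read_bed6(file.path(dir, "clusters.bed"))
  expect_equal(clusters2$start, b$clusters$start)
  anatomy <- read_tsv_table(file.path(dir, "pgf_anatomy.tsv"))
  expect_equal(anatomy$tsd_length, 10L)
  reads2 <- read_fasta(file.path(dir, "reads.fa"))
  expect_equal(unname(reads2), b$reads)
})

test_that("expression simulation plants the configured shifts", {
  cfg <- sim_config("minimal")
  et <- simulate_expression(sprintf("t%02d", 1:50), sprintf("l%02d", 1:50),
                            cfg, seed = 7)
  gr <- attr(et, "groups")
  expect_equal(nrow(et), 50 + 50 + cfg$expression$n_non_targets)
  expect_equal(mean(et$log2fc[gr == "top"]), cfg$expression$effect_size_top,
               tolerance = 0.25)
  expect_equal(mean(et$log2fc[gr == "non"]), 0, tolerance = 0.15)
  expect_true(all(et$padj >= 0 & et$padj <= 1))
  # null effect: top and non-target distributions indistinguishable
  cfg0 <- cfg
  cfg0$expression$effect_size_top <- 0
  cfg0$expression$effect_size_lower <- 0
  ps <- vapply(1:20, function(s) {
    e <- simulate_expression(sprintf("t%02d", 1:50), character(0), cfg0,
                             seed = 300 + s)
    g <- attr(e, "groups")
    ks_two_sample(e$log2fc[g == "top"], e$log2fc[g == "non"])$p_value
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
})
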