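test_that("map_perfect equals a naive all-window scan", {
  set.seed(17)
  genome <- c(chr1 = random_dna(8000), chr2 = random_dna(4000))
  picks <- c(substr(genome[1], 101, 130), substr(genome[1], 2001, 2028),
             revcomp(substr(genome[2], 501, 530)))
  # duplicate one sequence within the genome to create a multi-mapper
  genome[1] <- paste0(genome[1], substr(genome[1], 101, 130))
  seqs <- unique(c(picks, replicate(20, random_dna(30))))
  pool <- make_pool(seqs)
  hits <- map_perfect(pool, genome)
  ref <- naive_genome_hits(seqs, genome)
  got <- hits[order(hits$sequence, hits$chrom, hits$start, hits$strand),
              c("sequence", "chrom", "start", "strand")]
  expect_equal(got, ref, ignore_attr = TRUE)
  # weight shares of each sequence sum to 1; the duplicate gets 1/2 each
  shares <- tapply(hits$weight_share, hits$sequence, sum)
  expect_true(all(abs(shares - 1) < 1e-12))
  dup <- hits[hits$sequence == picks[1], ]
  expect_equal(nrow(dup), 2L)
  expect_equal(dup$weight_share, c(0.5, 0.5))
  # minus-strand hit: 5' end is the right edge
  mh <- hits[hits$strand == "-", ][1, ]
  expect_equal(mh$five_prime, mh$end)
  # unmapped sequences are flagged, not dropped silently
  expect_true(length(attr(hits, "unmapped")) > 0)
})

test_that("attribute_sources assigns by 5'-end containment and validates input", {
  hits <- data.frame(sequence = c("s1", "s2", "s2"), chrom = "chr1",
                     start = c(150L, 120L, 900L), end = c(179L, 149L, 929L),
                     strand = "+", five_prime = c(150L, 120L, 900L),
                     n_hits = c(1L, 2L, 2L), weight_share = c(1, 0.5, 0.5))
  clusters <- data.frame(cluster_id = "c1", chrom = "chr1", start = 100L,
                         end = 400L, score = 0L, strand = "+")
  sw <- attribute_sources(hits, clusters)
  expect_equal(sw$share[sw$sequence == "s1" & sw$source_label == "c1"], 1)
  expect_equal(sort(sw$share[sw$sequence == "s2"]), c(0.5, 0.5))
  expect_setequal(sw$source_label[sw$sequence == "s2"], c("c1", "NON_PIC"))
  overlapping <- rbind(clusters,
                       data.frame(cluster_id = "c2", chrom = "chr1",
                                  start = 300L, end = 500L, score = 0L,
                                  strand = "+"))
  expect_error(attribute_sources(hits, overlapping), "overlapping")
})

test_that("decompose_gene partitions weight with the <5% minor rule", {
  st <- data.frame(pirna = c("p1", "p2", "p3"), gene_id = "g1",
                   start = c(1L, 30L, 60L), end = c(20L, 49L, 79L),
                   mismatch_count = 0L, mismatch_positions = "",
                   slice_pos = 1L, count = c(81L, 15L, 4L))
  sw <- data.frame(sequence = c("p1", "p2", "p3"),
                   source_label = c("cA", "cB", "cC"), share = 1)
  dec <- decompose_gene("g1", st, sw)
  expect_equal(sum(dec$entries$fraction), 1)
  expect_equal(unname(dec$summary["top"]), 0.81)
  expect_equal(unname(dec$summary["second"]), 0.15)
  expect_equal(unname(dec$summary["third"]), 0)
  expect_equal(unname(dec$summary["minor_lt5"]), 0.04)
  expect_equal(unname(sum(dec$summary)), 1)
  # all weight from one cluster
  one <- decompose_gene("g1", st[1, ], sw)
  expect_equal(unname(one$summary["top"]), 1)
  # weight conservation: entries sum to the gene's targeting weight
  expect_equal(sum(dec$entries$weight), 100)
  expect_error(decompose_gene("nope", st, sw), "not in site table")
  # unmapped piRNAs excluded by default, included on request
  sw2 <- sw[-3, ]
  d2 <- decompose_gene("g1", st, sw2)
  expect_false("UNMAPPED" %in% d2$entries$source_label)
  expect_equal(sum(d2$entries$weight), 96)
  d3 <- decompose_gene("g1", st, sw2, include_unmapped = TRUE)
  expect_equal(d3$entries$weight[d3$entries$source_label == "UNMAPPED"], 4)
})

test_that("duplicating a locus halves per-hit shares but not per-piRNA totals", {
  set.seed(23)
  core <- random_dna(2000)
  pirna <- substr(core, 501, 530)
  g1 <- c(chr1 = core)
  g2 <- c(chr1 = paste0(core, random_dna(50), substr(core, 401, 700)))
  pool <- make_pool(pirna)
  h1 <- map_perfect(pool, g1)
  h2 <- map_perfect(pool, g2)
  expect_equal(h1$weight_share, 1)
  expect_equal(h2$weight_share, c(0.5, 0.5))
  expect_equal(sum(h1$weight_share), sum(h2$weight_share))
})

test_that("cis and trans labels follow genomic overlap with the target exons", {
  set.seed(31)
  fix <- toy_transcriptome(31)
  tx1 <- fix$transcripts$g1
  # cis piRNA: antisense to g1 within its second exon (genomic 601..900)
  cis_read <- revcomp(substr(fix$genome[[1]], 651, 680))
  # trans piRNA: junction-spanning antisense fragment placed far away (a
  # single-exon fragment would also map inside the gene and stay cis)
  frag <- substr(tx1$sequence, 550, 700)
  genome <- c(chr1 = paste0(fix$genome[[1]], random_dna(100), revcomp(frag),
                            random_dna(100)))
  trans_read <- revcomp(substr(tx1$sequence, 590, 619))
  pool <- make_pool(c(cis_read, trans_read))
  idx <- build_seed_index(fix$transcripts)
  st <- match_pool(pool, idx)
  expect_setequal(unique(st$gene_id), "g1")
  hits <- map_perfect(pool, genome)
  lab <- classify_cis_trans(st, hits, fix$models)
  expect_equal(lab$label[lab$pirna == cis_read], "cis")
  expect_equal(lab$label[lab$pirna == trans_read], "trans")
  expect_equal(attr(lab, "trans_fraction"), 0.5)
})
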