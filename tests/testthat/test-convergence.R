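make_site_table <- function(pirna, gene_id, start, count,
                            params = match_params()) {
  n <- length(start)
  data.frame(pirna = pirna, gene_id = gene_id, start = start,
             end = start + params$window_length - 1L,
             mismatch_count = rep(0L, n), mismatch_positions = rep("", n),
             slice_pos = start + params$window_end - 10L, count = count)
}

test_that("targeting_fraction is the weighted share of site-bearing piRNAs", {
  pool <- make_pool(c(strrep("AC", 14), strrep("GT", 14)), c(3L, 1L))
  none <- make_site_table(character(0), character(0), integer(0), integer(0))
  expect_equal(targeting_fraction(pool, none), 0)
  all_st <- make_site_table(pool$records$sequence, "g1", c(1L, 5L),
                            pool$records$count)
  expect_equal(targeting_fraction(pool, all_st), 1)
  one <- make_site_table(strrep("AC", 14), "g1", 1L, 3L)
  expect_equal(targeting_fraction(pool, one), 0.75)
  expect_error(targeting_fraction(collapse_reads(character(0)), one), "empty")
})

test_that("aggregate_by_gene distributes weight by policy and sums to 1", {
  a <- strrep("ACGTACG", 4)
  b <- strrep("TGCATGC", 4)
  st <- rbind(make_site_table(a, "g1", 1L, 10L),
              make_site_table(b, "g1", 40L, 6L),
              make_site_table(b, "g2", 7L, 6L))
  rt <- aggregate_by_gene(st, "split")
  expect_equal(sum(rt$fraction), 1)
  expect_equal(rt$weight[rt$gene_id == "g1"], 13) # 10 + 6/2
  expect_equal(rt$weight[rt$gene_id == "g2"], 3)
  rt_full <- aggregate_by_gene(st, "full")
  expect_equal(sum(rt_full$fraction), 1)
  expect_equal(rt_full$fraction[rt_full$gene_id == "g1"], 16 / 22)
  # a single piRNA targeting one gene carries fraction 1 and its full weight
  solo <- aggregate_by_gene(make_site_table(a, "g1", 3L, 10L))
  expect_equal(solo$fraction, 1)
  expect_equal(solo$weight, 10)
  # overlapping sites of one piRNA are not double counted in weight,
  # but they do extend the covered span
  two_sites <- rbind(make_site_table(a, "g1", 1L, 10L),
                     make_site_table(a, "g1", 11L, 10L))
  agg <- aggregate_by_gene(two_sites)
  expect_equal(agg$weight, 10)
  expect_equal(agg$span_nt, 30)
  expect_error(aggregate_by_gene(st, "nonsense"))
})

test_that("span is bounded by a single window for one site", {
  st <- make_site_table(strrep("AC", 14), "g1", 17L, 2L)
  expect_equal(aggregate_by_gene(st)$span_nt, match_params()$window_length)
})

test_that("top_target_set is the smallest prefix reaching coverage", {
  rt <- data.frame(gene_id = c("a", "b", "c"), weight = c(5, 3, 2),
                   fraction = c(0.5, 0.3, 0.2), rank = 1:3,
                   span_nt = 20, n_unique_pirnas = 1)
  expect_equal(top_target_set(rt, 0.7), c("a", "b"))
  expect_equal(top_target_set(rt, 1.0), c("a", "b", "c"))
  expect_equal(top_target_set(rt, 0.5), "a")
})

test_that("metagene binning matches a brute-force oracle and conserves mass", {
  fix <- toy_transcriptome(13)
  tx <- fix$transcripts$g1
  # uniform 5'-end positions across the transcript
  pos <- seq(21L, tx$length, by = 1L)
  st <- data.frame(pirna = "x", gene_id = "g1", start = pos - 19L, end = pos,
                   mismatch_count = 0L, mismatch_positions = "",
                   slice_pos = pos - 9L, count = 1L)
  mg <- metagene_profile(st, fix$transcripts, genes = "g1")
  expect_equal(sum(mg), 1, tolerance = 1e-12)
  # oracle: direct per-position binning
  fm <- feature_map(tx)
  flen <- c(`5UTR` = tx$utr5_len, CDS = tx$cds_len, `3UTR` = tx$utr3_len)
  fstart <- cumsum(c(0, flen[-3]))
  names(fstart) <- names(flen)
  ref <- matrix(0, 3, 20, dimnames = list(names(flen), NULL))
  for (p in pos) {
    f <- fm[p]
    off <- p - 1 - fstart[[f]]
    bin <- min(floor(20 * off / flen[[f]]), 19) + 1
    ref[f, bin] <- ref[f, bin] + 1
  }
  ref <- ref / sum(ref)
  expect_equal(unclass(mg), ref, ignore_attr = TRUE)
  # all sites on the first base of the 3'UTR land in 3'UTR bin 1
  p3 <- tx$utr5_len + tx$cds_len + 1L
  st3 <- st[st$end == p3, , drop = FALSE]
  mg3 <- metagene_profile(st3, fix$transcripts, genes = "g1")
  expect_equal(mg3["3UTR", 1], 1)
  expect_equal(sum(mg3), 1)
  # genes lacking a feature are excluded with a record
  no_cds <- fix$transcripts
  no_cds$g1$has_cds <- FALSE
  expect_error(metagene_profile(st, no_cds, genes = "g1"), "no eligible")
})

test_that("pool fractions scale to molecules per cell as reported", {
  expect_equal(molecules_per_cell(0.016, 1e7), 160000)
  expect_equal(molecules_per_cell(0.12 * 0.016, 1e7, round_thousand = TRUE),
               19000)
  expect_equal(molecules_per_cell(0), 0)
  expect_error(molecules_per_cell(-0.1), "fraction")
})
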