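bs_local_score <- function(a, b, scoring = align_scoring()) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                                mismatch = scoring$mismatch,
                                                baseOnly = TRUE)
  Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                Biostrings::DNAString(b), type = "local",
                                substitutionMatrix = m,
                                gapOpening = scoring$gap_open,
                                gapExtension = scoring$gap_ext,
                                scoreOnly = TRUE)
}

test_that("Smith-Waterman scores match an independent DP reference", {
  set.seed(41)
  for (i in 1:40) {
    a <- random_dna(sample(30:80, 1))
    b <- random_dna(sample(30:80, 1))
    # half the cases share a planted common segment to exercise alignment
    if (i %% 2 == 0) {
      seg <- random_dna(25)
      a <- paste0(substr(a, 1, 10), seg, substr(a, 20, nchar(a)))
      mseg <- seg
      substr(mseg, 12, 12) <- "A"
      b <- paste0(substr(b, 1, 5), mseg, substr(b, 15, nchar(b)))
    }
    got <- piswarm:::sw_align_cpp(a, b, 2, -3, 5, 2)
    expect_equal(got$score, bs_local_score(a, b), tolerance = 1e-9)
  }
})

test_that("local_align reports identity, orientation and query-disjoint hits", {
  set.seed(43)
  x <- random_dna(100)
  self <- local_align(x, x)
  expect_equal(self[[1]]$percent_identity, 100)
  expect_equal(self[[1]]$query_interval, c(1, 100))
  expect_equal(self[[1]]$strand_relation, "sense")
  # 5 substitutions in a 100-mer: 95% identity over 100 columns
  y <- x
  for (p in c(10, 30, 50, 70, 90)) {
    substr(y, p, p) <- setdiff(c("A", "C", "G", "T"), substr(x, p, p))[1]
  }
  al <- local_align(y, x)[[1]]
  expect_equal(al$n_columns, 100)
  expect_equal(al$percent_identity, 95)
  # antisense orientation is detected and mapped back to forward coordinates
  ra <- local_align(revcomp(x), x)[[1]]
  expect_equal(ra$strand_relation, "antisense")
  expect_equal(ra$percent_identity, 100)
  expect_equal(ra$query_interval, c(1, 100))
  # two separated copies give two query-disjoint alignments
  two <- paste0(random_dna(40), substr(x, 1, 50), random_dna(60),
                revcomp(substr(x, 51, 100)), random_dna(40))
  als <- local_align(two, x)
  expect_gte(length(als), 2)
  qi <- do.call(rbind, lapply(als, `[[`, "query_interval"))
  qi <- qi[order(qi[, 1]), ]
  expect_true(all(qi[-1, 1] > qi[-nrow(qi), 2]))
  expect_error(local_align("", x), "empty")
})

test_that("alignment identity is symmetric under symmetric scoring", {
  set.seed(47)
  for (i in 1:10) {
    a <- random_dna(60)
    b <- a
    for (p in sample(60, 6)) {
      substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    ab <- local_align(a, b)
    ba <- local_align(b, a)
    expect_equal(ab[[1]]$percent_identity, ba[[1]]$percent_identity)
    expect_equal(ab[[1]]$score, ba[[1]]$score)
  }
})

test_that("scan_pgf recovers an exact antisense copy of exons 3-5", {
  set.seed(53)
  genome <- c(chr1 = random_dna(6000))
  g <- gene_model("src", "chr1", "+",
                  data.frame(start = c(101, 601, 1101, 1601, 2101, 2601),
                             end = c(400, 900, 1400, 1900, 2400, 2900)),
                  cds_span = c(201, 2800))
  txs <- build_transcriptome(list(src = g), genome)
  pos <- which(txs$src$exon_index %in% 3:5)
  frag <- substr(txs$src$sequence, min(pos), max(pos))
  cluster <- paste0(random_dna(300), revcomp(frag), random_dna(300))
  hits <- scan_pgf(cluster, txs, list(src = g), genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$gene_id, "src")
  expect_equal(hits$strand_relation, "antisense")
  expect_equal(hits$exons_covered, "3,4,5")
  expect_equal(hits$processed_state, "processed")
  expect_true(hits$five_prime_truncated)
  expect_gt(hits$percent_identity, 99.9)
  expect_lte(abs(hits$q_start - 301), 3)
  # a random cluster yields no hits
  expect_equal(nrow(scan_pgf(random_dna(2000), txs, list(src = g), genome)), 0L)
})

test_that("detect_tsd finds planted duplications exactly and maximally", {
  set.seed(59)
  plant <- function(tsd_len, insert_len = 300) {
    repeat {
      left <- random_dna(200)
      insert <- random_dna(insert_len)
      right <- random_dna(200)
      tsd <- substr(right, 1, tsd_len)
      g <- paste0(left, tsd, insert, tsd, substr(right, tsd_len + 1, 200))
      s <- 200 + tsd_len + 1
      e <- 200 + tsd_len + insert_len
      # reject placements whose duplication extends by flank coincidence
      if (substr(g, s - tsd_len - 1, s - tsd_len - 1) != substr(insert, insert_len, insert_len) &&
          substr(insert, 1, 1) != substr(g, e + tsd_len + 1, e + tsd_len + 1)) {
        return(list(g = g, s = s, e = e))
      }
    }
  }
  for (tsd_len in c(8L, 14L, 20L)) {
    f <- plant(tsd_len)
    r <- detect_tsd(f$g, f$s, f$e)
    expect_equal(r$repeat_length, tsd_len)
    left <- substr(f$g, r$left_copy[1], r$left_copy[2])
    right <- substr(f$g, r$right_copy[1], r$right_copy[2])
    expect_identical(left, right)
    # maximality: one more base on either end breaks the repeat
    expect_false(substr(f$g, r$left_copy[1] - 1, r$left_copy[2]) ==
                   substr(f$g, r$right_copy[1] - 1, r$right_copy[2]))
    expect_false(substr(f$g, r$left_copy[1], r$left_copy[2] + 1) ==
                   substr(f$g, r$right_copy[1], r$right_copy[2] + 1))
  }
  # random flanks: a spurious repeat of >= 8 nt is (almost) never called
  n_false <- 0L
  for (i in 1:30) {
    g <- random_dna(700)
    if (!is.null(detect_tsd(g, 301, 400))) n_false <- n_false + 1L
  }
  expect_lte(n_false, 1L)
  expect_error(detect_tsd(random_dna(100), 20, 90), "flank")
})

test_that("pairwise_identity tracks planted divergence and detects unrelatedness", {
  set.seed(61)
  a <- random_dna(1200)
  expect_equal(pairwise_identity(a, a)$identity, 100)
  b <- a
  mut <- sample(1200, 120)
  for (p in mut) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(a, p, p))[1]
  }
  r <- pairwise_identity(a, b)
  expect_true(r$comparable)
  expect_equal(r$identity, 90, tolerance = 0.02)
  u <- pairwise_identity(random_dna(500), random_dna(500), min_score = 60)
  expect_false(u$comparable)
  expect_true(is.na(u$identity))
})
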