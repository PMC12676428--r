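test_that("antisense_window takes the reverse complement of nt 2-21", {
  p <- match_params()
  pirna <- strrep("TACGT", 6) # 30 nt
  expect_equal(antisense_window(pirna, p),
               revcomp(substr(pirna, 2, 21)))
  # U is read as T
  expect_equal(antisense_window(chartr("T", "U", pirna), p),
               antisense_window(pirna, p))
  # a 20-nt piRNA cannot fill a window ending at nt 21
  expect_error(antisense_window(strrep("A", 20), p), "shorter")
  # involution: treating the window as a piRNA with an identity window
  # recovers the original subsequence
  w <- antisense_window(pirna, p)
  expect_equal(antisense_window(w, match_params(1, 20, 0)),
               substr(pirna, 2, 21))
})

test_that("mismatch rule: nt 1 exempt, <=1 mismatch in nt 2-21 tolerated", {
  set.seed(21)
  params <- match_params()
  pirna <- random_dna(28)
  base <- random_dna(400)
  tx0 <- embed_window(base, pirna, 150, 0L)
  s0 <- find_sites_bruteforce(pirna, tx0, params)
  expect_true(150 %in% s0$start)
  expect_equal(s0$mismatch_count[s0$start == 150], 0L)
  # site interval pairs the window, slice position faces piRNA nt 10
  expect_equal(s0$end[s0$start == 150], 169)
  expect_equal(s0$slice_pos[s0$start == 150], 150 + 21 - 10)
  # one substitution inside the window: still a site, with 1 mismatch at the
  # right piRNA coordinate; two substitutions: no site
  tx1 <- embed_window(base, pirna, 150, 1L)
  s1 <- find_sites_bruteforce(pirna, tx1, params)
  expect_equal(s1$mismatch_count[s1$start == 150], 1L)
  mm_pos <- as.integer(s1$mismatch_positions[s1$start == 150])
  expect_true(mm_pos >= 2 && mm_pos <= 21)
  # verify the reported coordinate: restoring that base restores 0 mismatches
  col <- 21 - mm_pos + 1 # window column of the mismatch
  fixed <- tx1
  substr(fixed, 150 + col - 1, 150 + col - 1) <-
    substr(antisense_window(pirna, params), col, col)
  expect_equal(find_sites_bruteforce(pirna, fixed, params)$mismatch_count[1], 0L)
  tx2 <- embed_window(base, pirna, 150, 2L)
  expect_false(150 %in% find_sites_bruteforce(pirna, tx2, params)$start)
  # a change opposite piRNA nt 1 is never evaluated: embed the window, then
  # mutate the base just 3' of it on the transcript (paired to nt 1)
  tx_nt1 <- tx0
  b <- substr(tx_nt1, 170, 170)
  substr(tx_nt1, 170, 170) <- setdiff(c("A", "C", "G", "T"), b)[1]
  s <- find_sites_bruteforce(pirna, tx_nt1, params)
  expect_equal(s$mismatch_count[s$start == 150], 0L)
})

test_that("N in the transcript never matches", {
  params <- match_params()
  pirna <- random_dna(26)
  tx <- embed_window(random_dna(200), pirna, 90, 0L)
  substr(tx, 95, 95) <- "N"
  s <- find_sites_bruteforce(pirna, tx, params)
  expect_equal(s$mismatch_count[s$start == 90], 1L)
})

test_that("indexed matching equals brute force, including shared windows", {
  set.seed(99)
  params <- match_params()
  txs <- setNames(replicate(5, random_dna(800)), paste0("t", 1:5))
  pirnas <- replicate(30, random_dna(sample(26:32, 1)))
  # plant hits at 0/1/2 mismatches and two piRNAs sharing one window
  txs[1] <- embed_window(txs[1], pirnas[1], 50, 0L)
  txs[2] <- embed_window(txs[2], pirnas[2], 300, 1L)
  txs[3] <- embed_window(txs[3], pirnas[3], 600, 2L)
  pirnas <- c(pirnas, paste0(substr(pirnas[1], 1, 21), "AAAAA"))
  pool <- make_pool(unique(pirnas), sample(1:5, length(unique(pirnas)), TRUE))
  idx <- build_seed_index(txs, params)
  got <- match_pool(pool, idx)
  ref <- match_pool_bruteforce(pool, txs, params)
  expect_equal(got, ref, ignore_attr = TRUE)
  expect_gt(nrow(got), 0)
})

test_that("short piRNAs are excluded and tallied; empty pool gives empty table", {
  idx <- build_seed_index(c(t1 = random_dna(300)))
  pool <- make_pool(c(random_dna(19), random_dna(28)))
  st <- match_pool(pool, idx)
  expect_equal(attr(st, "n_too_short"), 1L)
  empty <- collapse_reads(character(0))
  expect_equal(nrow(match_pool(empty, idx)), 0L)
})

test_that("raising the mismatch budget or trimming the window never loses sites", {
  set.seed(5)
  for (rep in 1:20) {
    tx <- c(t1 = random_dna(500))
    pirna <- random_dna(30)
    tx[1] <- embed_window(tx[1], pirna, sample(100, 1) + 50,
                          sample(0:2, 1), match_params())
    pool <- make_pool(pirna)
    s1 <- match_pool(pool, build_seed_index(tx, match_params(2, 21, 1)))
    s2 <- match_pool(pool, build_seed_index(tx, match_params(2, 21, 2)))
    expect_true(all(s1$start %in% s2$start))
    # shrinking the window keeps every site of the larger window (its
    # sub-window has no more mismatches than the budget)
    s3 <- match_pool(pool, build_seed_index(tx, match_params(2, 16, 1)))
    expect_true(all((s1$start + 5L) %in% s3$start))
  }
})
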