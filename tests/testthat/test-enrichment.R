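test_that("union coverage counts overlapping bases once", {
  expect_equal(union_bp(data.frame(seqname = character(), start = integer(),
                                   end = integer())), 0L)
  expect_equal(union_bp(data.frame(seqname = "c", start = c(0, 5),
                                   end = c(10, 15))), 15L)
  set.seed(31)
  for (i in 1:5) {
    iv <- random_intervals(200, seqnames = c("chr1", "chr2"))
    expect_equal(union_bp(iv), oracle_union_bp(iv))
    expect_equal(union_bp(iv[sample.int(nrow(iv)), ]), oracle_union_bp(iv))
  }
  # equality with the summed lengths iff pairwise disjoint
  disj <- data.frame(seqname = "c", start = c(0, 20), end = c(10, 30))
  expect_equal(union_bp(disj), sum(disj$end - disj$start))
})

test_that("overlap counting is >=1 bp, per-entity, and asymmetric", {
  p <- data.frame(seqname = "c", start = 0, end = 100)
  f <- data.frame(seqname = "c", start = c(50, 200), end = c(60, 210))
  expect_equal(unname(overlap_counts(p, f)), c(1L, 1L))
  expect_equal(unname(overlap_counts(p, data.frame(seqname = "c",
                                                   start = 500, end = 510))),
               c(0L, 0L))
  # one peak covering two features: (1, 2), not symmetric under role swap
  f2 <- data.frame(seqname = "c", start = c(10, 40), end = c(20, 50))
  expect_equal(unname(overlap_counts(p, f2)), c(1L, 2L))
  expect_equal(unname(overlap_counts(f2, p)), c(2L, 1L))
  set.seed(13)
  for (i in 1:5) {
    a <- random_intervals(40)
    b <- random_intervals(25)
    expect_equal(unname(overlap_counts(a, b)), oracle_overlap_counts(a, b))
  }
})

test_that("GC content is computed over the peak union, excluding N", {
  genome <- Biostrings::DNAStringSet(c(g = "ATATATGCGCNNNN"))
  expect_equal(gc_percent(data.frame(seqname = "g", start = 0, end = 4),
                          genome), 0)
  expect_equal(gc_percent(data.frame(seqname = "g", start = 4, end = 8),
                          genome), 50)
  # N-only span contributes nothing to the denominator
  expect_equal(gc_percent(data.frame(seqname = "g", start = c(6, 10),
                                     end = c(10, 14)), genome), 100)
  expect_error(gc_percent(data.frame(seqname = "g", start = 10, end = 20),
                          genome), "bounds")
  set.seed(8)
  chars <- sample(c("A", "C", "G", "T"), 500, replace = TRUE)
  genome2 <- Biostrings::DNAStringSet(c(r = paste(chars, collapse = "")))
  pk <- data.frame(seqname = "r", start = c(10, 100), end = c(60, 300))
  covered <- c(11:60, 101:300)
  expect_equal(gc_percent(pk, genome2),
               round(100 * mean(chars[covered] %in% c("C", "G")), 1))
})

test_that("fold change reproduces the published ratios at print precision", {
  expect_equal(attr(fold_change(752369, 464876), "printed"), "1.62")
  expect_equal(attr(fold_change(96, 50), "printed"), "1.92")
  expect_equal(as.numeric(fold_change(5, 5)), 1)
  expect_equal(attr(fold_change(6, 5), "printed"), "1.2")
  expect_error(fold_change(5, 0), "> 0")
})

test_that("the ledger fills every cell and is ordering-invariant", {
  set.seed(2)
  mock <- random_intervals(50, space = 50000)
  treated <- random_intervals(80, space = 50000)
  feats <- list(g4 = random_intervals(30, space = 50000))
  led <- build_ledger(mock, treated, feats)
  expect_s3_class(led, "enrichment_ledger")
  expect_equal(led$conditions$n_peaks, c(50L, 80L))
  expect_equal(led$conditions$mean_peak_length,
               as.integer(round(led$conditions$total_bp_covered /
                                  led$conditions$n_peaks)))
  led2 <- build_ledger(mock[sample.int(50), ], treated[sample.int(80), ],
                       feats)
  expect_equal(led, led2)
  # identical conditions give unit fold changes
  same <- build_ledger(mock, mock, feats)
  expect_true(all(same$fold_changes$value == 1))
  # reciprocal folds multiply to one exactly before rounding
  swapped <- build_ledger(treated, mock, feats)
  expect_equal(unname(led$fold_changes$value * swapped$fold_changes$value),
               rep(1, 2))
})

test_that("top-N selection is score-ordered with coordinate tie-breaks", {
  pk <- data.frame(seqname = "c", start = c(100, 0, 50, 200),
                   end = c(110, 10, 60, 210), score = c(5, 3, 3, 1))
  expect_equal(nrow(top_n_peaks(pk, 4)), 4L)
  top2 <- top_n_peaks(pk, 2)
  expect_equal(sort(top2$score), c(3, 5))
  expect_equal(top2$start[top2$score == 3], 0)  # leftmost of the tied pair
  expect_warning(out <- top_n_peaks(pk, 10), "exceeds")
  expect_equal(nrow(out), 4L)
  expect_error(top_n_peaks(pk[, 1:3], 2), "score")
  set.seed(3)
  big <- random_intervals(400, space = 1e6)
  big$score <- sample.int(5000, 400)
  top <- top_n_peaks(big, 100)
  expect_equal(sort(top$score, decreasing = TRUE),
               sort(big$score, decreasing = TRUE)[1:100])
})

test_that("the pseudo-replicate ratio applies the factor-of-2 rule", {
  r <- reproducibility_ratio(344, 527)
  expect_equal(r$ratio, 1.53)
  expect_true(r$reliable)
  r2 <- reproducibility_ratio(568, 538)
  expect_equal(r2$ratio, 0.95)
  expect_true(r2$reliable)
  expect_false(reproducibility_ratio(100, 700)$reliable)
  expect_false(reproducibility_ratio(100, 49)$reliable)
  expect_true(reproducibility_ratio(100, 50)$reliable)
  expect_true(reproducibility_ratio(100, 200)$reliable)
  expect_error(reproducibility_ratio(0, 10), "> 0")
})
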