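test_that("planted-motif genomes scan to exactly the truth set", {
  g <- gen_genome_with_motifs(sim_config(seed = 1, genome_length = 10000,
                                         n_planted_motifs = 5))
  expect_equal(nrow(g$truth), 5L)
  got <- scan_sequence(g$sequence)
  expect_equal(got$start, g$truth$start)
  expect_equal(got$end, g$truth$end)
  expect_equal(got$strand, g$truth$strand)
  expect_setequal(g$truth$strand, c("+", "-"))  # half per strand
  expect_true(all(g$truth$end <= nchar(g$sequence)))
})

test_that("a GC-free genome is A/T only and motif-free", {
  g <- gen_genome_with_motifs(sim_config(seed = 2, gc_fraction = 0,
                                         n_planted_motifs = 0,
                                         genome_length = 5000))
  expect_false(grepl("[GC]", g$sequence))
  expect_equal(nrow(scan_sequence(g$sequence)), 0L)
})

test_that("generators are pure functions of their configuration", {
  cfg <- sim_config(seed = 9, genome_length = 8000, n_planted_motifs = 4)
  expect_identical(gen_genome_with_motifs(cfg), gen_genome_with_motifs(cfg))
  cfg2 <- small_fiber_config(9, n_molecules = 5)
  expect_identical(gen_fiber_field(cfg2), gen_fiber_field(cfg2))
  expect_identical(gen_tract_sample(cfg), gen_tract_sample(cfg))
  fe <- gen_features(cfg)
  expect_identical(gen_peak_experiment(cfg, fe), gen_peak_experiment(cfg, fe))
})

test_that("infeasible motif placement raises an explicit error", {
  expect_error(gen_genome_with_motifs(sim_config(seed = 1,
                                                 genome_length = 200,
                                                 n_planted_motifs = 10)),
               "too small")
})

test_that("peak replicates share the configured fraction of true peaks", {
  cfg <- sim_config(seed = 4, replicate_shared_fraction = 1)
  fe <- gen_features(cfg)
  pe <- gen_peak_experiment(cfg, fe)
  expect_identical(pe$peaks$mock$rep1, pe$peaks$mock$rep2)
  expect_equal(nrow(pe$peaks$mock$rep1), cfg$n_peaks_per_replicate)
  expect_true(all(c("score") %in% names(pe$peaks$treated$rep1)))

  cfg2 <- sim_config(seed = 4, replicate_shared_fraction = 0.5)
  pe2 <- gen_peak_experiment(cfg2, fe)
  key <- function(df) paste(df$start, df$end)
  shared <- length(intersect(key(pe2$peaks$mock$rep1),
                             key(pe2$peaks$mock$rep2)))
  expect_equal(shared, 200L)
})

test_that("an empty feature set with enrichment > 1 is rejected", {
  cfg <- sim_config(seed = 1, feature_enrichment = 2)
  empty <- data.frame(seqname = character(), start = integer(),
                      end = integer())
  expect_error(gen_peak_experiment(cfg, empty), "empty feature set")
})

test_that("configured feature enrichment is recovered from the ledger", {
  pooled_counts <- function(enrichment, seeds) {
    m <- 0; t <- 0
    for (s in seeds) {
      cfg <- sim_config(seed = s, feature_enrichment = enrichment)
      fe <- gen_features(cfg)
      pe <- gen_peak_experiment(cfg, fe)
      led <- build_ledger(pe$truth$true_peaks$mock,
                          pe$truth$true_peaks$treated, list(g4 = fe))
      m <- m + led$conditions$g4_within_peaks[1]
      t <- t + led$conditions$g4_within_peaks[2]
    }
    t / m
  }
  expect_lt(abs(pooled_counts(2, 1:10) - 2), 0.5)    # within 25% of 2
  expect_lt(abs(pooled_counts(1, 101:110) - 1), 0.25)  # exchangeable
})

test_that("fiber-field dot counts follow the stated Poisson model", {
  # zero damage: no truth dots, and the detector reports a zero rate
  f0 <- gen_fiber_field(small_fiber_config(5), damage_rate = 0)
  expect_equal(nrow(f0$truth$dots), 0L)
  expect_error(gen_fiber_field(small_fiber_config(5), damage_rate = -1),
               ">= 0")
  # total dots within 3 SD of the Poisson expectation from truth lengths
  f <- gen_fiber_field(small_fiber_config(6, n_molecules = 60,
                                          image_size = 1024L),
                       damage_rate = 100)
  lambda <- sum(f$truth$lengths_um) * 3000e-6 * 100
  expect_lt(abs(nrow(f$truth$dots) - lambda), 3 * sqrt(lambda))
  # truth dots lie on their molecules (within jitter) and inside the frame
  expect_true(all(f$truth$dots$x >= 1 & f$truth$dots$x <= 1024 &
                    f$truth$dots$y >= 1 & f$truth$dots$y <= 1024))
  d <- f$truth$dots
  seg_dist <- vapply(seq_len(nrow(d)), function(i) {
    poly <- f$truth$molecules[[d$molecule[i]]]
    segs <- cbind(1, poly[-nrow(poly), 1], poly[-nrow(poly), 2],
                  poly[-1, 1], poly[-1, 2])
    sqrt(min(g4pombe:::point_seg_dist2(d$x[i], d$y[i], segs)))
  }, numeric(1))
  expect_lt(max(seg_dist), 3)
})

test_that("molecule curvature stays within the stretched-DNA bound", {
  f <- gen_fiber_field(small_fiber_config(7, n_molecules = 10))
  for (poly in f$truth$molecules) {
    d <- diff(poly)
    ang <- atan2(d[, 2], d[, 1])
    turn <- abs(diff(ang))
    turn <- pmin(turn, 2 * pi - turn)
    expect_lt(max(turn), pi / 12 + 1e-9)
  }
})

test_that("tract samples match their generating parameters", {
  cfg <- sim_config(seed = 4, tract_n = c(control = 1000L, treated = 1000L))
  tr <- gen_tract_sample(cfg)
  # 60 kb mean at 2 kb/um -> 30 um, within 5% at n = 1000
  expect_lt(abs(mean(tr$samples_um$control) - 30) / 30, 0.05)
  expect_true(all(tr$samples_um$control > 0))
  # degenerate sd: all values equal
  cfg0 <- sim_config(seed = 5, tract_sd = c(control = 0, treated = 0))
  tr0 <- gen_tract_sample(cfg0)
  expect_equal(length(unique(tr0$samples_um$control)), 1L)
  expect_equal(unique(tr0$samples_um$treated), 20)  # 40 kb / 2 kb/um
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(gc_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(n_molecules = 0), "positive")
  expect_error(sim_config(loop_length_range = c(1, 30)), "25")
  expect_error(sim_config(damage_rate = -2), ">= 0")
})
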