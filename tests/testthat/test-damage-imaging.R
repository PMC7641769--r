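# Build a deterministic field around known geometry (no generator): one
# straight horizontal molecule rendered through the package's own optics.
straight_field <- function(n_px = 100, sz = 256L, noise_sd = 50,
                           amp = 250, pixel_size = 0.16, seed = 1) {
  set.seed(seed)
  poly <- cbind(x = seq(60, 60 + n_px - 1), y = rep(128, n_px))
  backbone <- g4pombe:::render_polylines(list(poly), sz, 1.2, amp) +
    matrix(rnorm(sz * sz, 500, noise_sd), sz, sz)
  list(backbone = backbone,
       damage = matrix(rnorm(sz * sz, 500, noise_sd), sz, sz),
       pixel_size = pixel_size, poly = poly)
}

test_that("a blank noise-only field yields no traces and no dots", {
  set.seed(2)
  blank <- list(backbone = matrix(rnorm(256 * 256, 500, 50), 256, 256),
                damage = matrix(rnorm(256 * 256, 500, 50), 256, 256),
                pixel_size = 0.16)
  expect_equal(trace_molecules(blank), list())
  expect_equal(nrow(detect_dots(blank)), 0L)
  flat <- list(backbone = matrix(0, 64, 64), damage = matrix(0, 64, 64),
               pixel_size = 0.16)
  expect_equal(trace_molecules(flat), list())
  expect_equal(nrow(detect_dots(flat)), 0L)
})

test_that("a straight 100 px segment traces to its known length", {
  f <- straight_field()
  tr <- trace_molecules(f)
  expect_equal(length(tr), 1L)
  expect_lt(abs(tr[[1]]$length_um - 16), 0.5)  # 100 px at 0.16 um/px
})

test_that("tracing and detection are invariant to a constant offset", {
  f <- straight_field(seed = 4)
  f_off <- f
  f_off$backbone <- f$backbone + 300
  f_off$damage <- f$damage + 300
  expect_equal(trace_molecules(f), trace_molecules(f_off))
  expect_equal(detect_dots(f), detect_dots(f_off))
})

test_that("a single rendered spot is detected within a pixel", {
  set.seed(6)
  sz <- 128L
  dmg <- g4pombe:::render_spots(data.frame(x = 50, y = 60, molecule = 1),
                                sz, 1.2, 250) +
    matrix(rnorm(sz * sz, 500, 50), sz, sz)
  d <- detect_dots(list(damage = dmg, pixel_size = 0.16))
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - 50), 1)
  expect_lt(abs(d$y - 60), 1)
})

test_that("planted dots are recovered with recall and precision >= 0.9", {
  f <- gen_fiber_field(small_fiber_config(11, n_molecules = 20,
                                          image_size = 1024L),
                       damage_rate = 150)
  d <- detect_dots(f)
  truth <- f$truth$dots
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any((d$x - truth$x[i])^2 + (d$y - truth$y[i])^2 <= 4)
  }, logical(1))
  used <- vapply(seq_len(nrow(d)), function(i) {
    any((truth$x - d$x[i])^2 + (truth$y - d$y[i])^2 <= 4)
  }, logical(1))
  expect_gte(mean(matched), 0.9)  # recall
  expect_gte(mean(used), 0.9)    # precision
})

test_that("planted molecules are recovered with accurate lengths", {
  cfg <- small_fiber_config(21, n_molecules = 15, image_size = 1024L,
                            molecule_length_mean = 10,
                            molecule_length_sd = 2)
  f <- gen_fiber_field(cfg)
  tr <- trace_molecules(f)
  truth_len <- f$truth$lengths_um[f$truth$lengths_um >= 5]
  expect_gte(length(tr), length(truth_len) - 1L)
  # match each trace to the nearest truth molecule by midpoint distance
  errs <- vapply(tr, function(t) {
    mid <- t$polyline[ceiling(nrow(t$polyline) / 2), ]
    d2 <- vapply(seq_along(f$truth$molecules), function(i) {
      poly <- f$truth$molecules[[i]]
      min((poly[, 1] - mid[1])^2 + (poly[, 2] - mid[2])^2)
    }, numeric(1))
    i <- which.min(d2)
    abs(t$length_um - f$truth$lengths_um[i]) / f$truth$lengths_um[i]
  }, numeric(1))
  expect_lt(max(errs), 0.1)
})

test_that("damage arithmetic follows the 3000 bp/um conversion exactly", {
  # 3 dots on one 10 um molecule: 0.3 dots/um = 100 dots/Mbp
  poly <- cbind(x = seq(10, 10 + 62.5 - 1, length.out = 64), y = rep(20, 64))
  tr <- list(list(id = 1L, polyline = poly,
                  length_um = g4pombe:::polyline_length(poly) * 0.16))
  dots <- data.frame(x = c(15, 30, 45), y = c(20, 20.5, 19.5))
  s <- assign_and_quantify(tr, dots, pixel_size = 0.16)
  expect_equal(s$per_molecule$dot_count, 3L)
  expect_equal(s$pooled_dots_per_um, 3 / tr[[1]]$length_um)
  expect_equal(s$pooled_dots_per_mbp, s$pooled_dots_per_um / 3000e-6)
  expect_equal(s$per_molecule$dots_per_mbp / s$per_molecule$dots_per_um,
               1e6 / 3000)
  # far dots are excluded, zero dots give a zero rate
  far <- data.frame(x = 15, y = 40)
  s2 <- assign_and_quantify(tr, far, pixel_size = 0.16)
  expect_equal(s2$n_unassigned, 1L)
  expect_equal(s2$pooled_dots_per_mbp, 0)
  expect_error(assign_and_quantify(tr, dots, 0.16, bp_per_um = 0), "> 0")
})

test_that("zero-damage fields report zero rates (false-positive control)", {
  zeros <- vapply(1:8, function(s) {
    f <- gen_fiber_field(small_fiber_config(s + 40), damage_rate = 0)
    tr <- trace_molecules(f)
    d <- detect_dots(f)
    assign_and_quantify(tr, d, f$pixel_size)$pooled_dots_per_mbp
  }, numeric(1))
  expect_gte(mean(zeros == 0), 7 / 8)
})

test_that("condition summaries handle degenerate and swapped inputs", {
  a <- list(10, 10, 10)
  b <- list(10, 10, 10)
  out <- summarize_conditions(list(ctrl = a, drug = b), control = "ctrl")
  expect_equal(out$fold_vs_control, c(1, 1))
  expect_equal(out$p_value[out$condition == "drug"], 1)

  x <- list(10, 11, 9)
  y <- list(31, 29, 33)
  fwd <- summarize_conditions(list(ctrl = x, drug = y), control = "ctrl")
  rev <- summarize_conditions(list(ctrl = x, drug = y), control = "drug")
  f1 <- fwd$fold_vs_control[fwd$condition == "drug"]
  f2 <- rev$fold_vs_control[rev$condition == "ctrl"]
  expect_equal(f1 * f2, 1)
  expect_lt(fwd$p_value[fwd$condition == "drug"], 0.01)
  expect_warning(summarize_conditions(list(ctrl = list(10), drug = list(20)),
                                      control = "ctrl"), "single replicate")
})
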