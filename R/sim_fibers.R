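#' Generate a synthetic two-channel fiber field
#'
#' Emulates a fluorescence image of stretched DNA molecules: the backbone
#' channel holds near-linear molecules (random walks with turns bounded at
#' 15 degrees per 10 px step) rendered at the configured point-spread sigma
#' over Gaussian background noise; the damage channel holds
#' diffraction-limited dots placed on the molecules, the count per molecule
#' drawn as Poisson with mean `damage_rate x length_um x bp_per_um x 1e-6`
#' and positions jittered by 0.5 px. Truth records the molecule polylines,
#' lengths and exact dot coordinates.
#'
#' @param config A [sim_config()].
#' @param damage_rate Planted dots/Mbp; defaults to `config$damage_rate`.
#' @param stream RNG stream offset so replicate fields under one config
#'   differ while staying reproducible.
#' @return List: `backbone`, `damage` (intensity matrices in counts),
#'   `pixel_size`, and `truth` (`molecules` list of polylines as (x, y)
#'   matrices, `lengths_um`, `dots` data.frame with `x`, `y`, `molecule`,
#'   `planted_damage_rate`).
#' @export
gen_fiber_field <- function(config = sim_config(),
                            damage_rate = config$damage_rate, stream = 0L) {
  if (damage_rate < 0) stop("damage_rate must be >= 0")
  with_config_seed(config, 4L + stream, {
    n <- config$n_molecules
    px <- config$pixel_size
    sz <- config$image_size
    if (sz * px < 2 * config$molecule_length_mean) {
      stop("image_size too small for the configured molecule lengths")
    }
    molecules <- vector("list", n)
    lengths_um <- numeric(n)
    dots <- list()
    for (i in seq_len(n)) {
      len_um <- max(config$min_molecule_length * 0.5,
                    rnorm(1, config$molecule_length_mean,
                          config$molecule_length_sd))
      poly <- draw_molecule(len_um / px, sz)
      molecules[[i]] <- poly
      lengths_um[i] <- polyline_length(poly) * px
      mbp <- lengths_um[i] * config$bp_per_um * 1e-6
      k <- rpois(1, damage_rate * mbp)
      if (k > 0) {
        pos <- sample_on_polyline(poly, runif(k))
        dots[[length(dots) + 1L]] <- data.frame(
          x = pos[, 1] + rnorm(k, 0, 0.5),
          y = pos[, 2] + rnorm(k, 0, 0.5), molecule = i)
      }
    }
    dots <- if (length(dots)) do.call(rbind, dots) else
      data.frame(x = numeric(), y = numeric(), molecule = integer())
    amp <- config$snr * config$background_noise_sd

    backbone <- render_polylines(molecules, sz, config$psf_sigma, amp)
    damage <- render_spots(dots, sz, config$psf_sigma, amp)
    noise <- function() matrix(rnorm(sz * sz, config$background_level,
                                     config$background_noise_sd), sz, sz)
    list(backbone = pmax(backbone + noise(), 0),
         damage = pmax(damage + noise(), 0),
         pixel_size = px,
         truth = list(molecules = molecules, lengths_um = lengths_um,
                      dots = dots, planted_damage_rate = damage_rate))
  })
}

# Bounded-curvature random walk: steps of 10 px, heading changes uniform in
# +/- 5 degrees (tightly stretched DNA is near-straight; wiggles sharper
# than the diffraction limit would be smoothed away by the PSF and make the
# rendered contour length disagree with the recorded truth), re-drawn
# wholesale if it leaves the frame margin. Turns never exceed 15 degrees
# per step.
draw_molecule <- function(len_px, sz, step = 10) {
  margin <- 6
  for (try in 1:100) {
    n_step <- ceiling(len_px / step)
    d <- len_px / n_step
    theta <- runif(1, 0, 2 * pi) +
      cumsum(c(0, runif(n_step - 1, -pi / 36, pi / 36)))
    x0 <- runif(1, margin, sz - margin)
    y0 <- runif(1, margin, sz - margin)
    x <- x0 + c(0, cumsum(d * cos(theta)))
    y <- y0 + c(0, cumsum(d * sin(theta)))
    if (all(x > margin & x < sz - margin & y > margin & y < sz - margin)) {
      return(cbind(x = x, y = y))
    }
  }
  stop("could not fit a molecule in the frame; increase image_size")
}

polyline_length <- function(poly) {
  if (nrow(poly) < 2) return(0)
  sum(sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2))
}

# Points at fractional arc-length positions along a polyline.
sample_on_polyline <- function(poly, frac) {
  seg <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  cum <- c(0, cumsum(seg))
  s <- frac * cum[length(cum)]
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i[i < 1] <- 1L
  i[i > length(seg)] <- length(seg)
  t <- (s - cum[i]) / seg[i]
  cbind(poly[i, 1] + t * (poly[i + 1, 1] - poly[i, 1]),
        poly[i, 2] + t * (poly[i + 1, 2] - poly[i, 2]))
}

# Render polylines as unit-density lines convolved with a Gaussian PSF.
# Points are laid every 0.25 px of arc so the line integral is ~1 per px
# independent of orientation; the pre-blur density is scaled so the blurred
# ridge peaks at `amp` (ridge peak of a blurred unit line = 1/(sqrt(2*pi)*s)).
render_polylines <- function(molecules, sz, psf_sigma, amp) {
  img <- matrix(0, sz, sz)
  scale <- amp * sqrt(2 * pi) * psf_sigma
  for (poly in molecules) {
    L <- polyline_length(poly)
    if (L <= 0) next
    n_pt <- max(2L, ceiling(L / 0.25))
    pts <- sample_on_polyline(poly, seq(0, 1, length.out = n_pt))
    step <- L / (n_pt - 1)
    cx <- pmin(pmax(round(pts[, 1]), 1), sz)
    cy <- pmin(pmax(round(pts[, 2]), 1), sz)
    idx <- cy + (cx - 1L) * sz  # row = y, col = x
    add <- tapply(rep(step * scale, length(idx)), idx, sum)
    ii <- as.integer(names(add))
    img[ii] <- img[ii] + as.numeric(add)
  }
  if (max(img) > 0) img <- blur_sep(img, psf_sigma)
  img
}

# Render point emitters: delta of mass amp*2*pi*sigma^2 then PSF blur, so
# each spot peaks at ~amp.
render_spots <- function(dots, sz, psf_sigma, amp) {
  img <- matrix(0, sz, sz)
  if (nrow(dots) == 0) return(img)
  cx <- pmin(pmax(round(dots$x), 1), sz)
  cy <- pmin(pmax(round(dots$y), 1), sz)
  idx <- cy + (cx - 1L) * sz
  mass <- amp * 2 * pi * psf_sigma^2
  add <- tapply(rep(mass, length(idx)), idx, sum)
  ii <- as.integer(names(add))
  img[ii] <- img[ii] + as.numeric(add)
  blur_sep(img, psf_sigma)
}
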