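#' Trace stretched-DNA molecules in a backbone channel
#'
#' Segments the backbone channel with a global noise-adaptive threshold
#' (median plus `k_bg` robust SDs of a lightly smoothed channel -- molecules
#' occupy so small an area fraction that a bimodal-histogram threshold such
#' as Otsu's collapses into the background mode), skeletonizes the mask
#' (Zhang-Suen thinning), labels connected skeleton components and extracts
#' each component's longest path (double breadth-first search), which
#' implicitly prunes short side branches. Arc length is measured along the
#' path and converted with the pixel size; molecules shorter than
#' `min_length_um` are discarded. Deterministic: no randomness is involved,
#' and a constant intensity offset does not change the result.
#'
#' @param field Fiber field list with `backbone` matrix and `pixel_size`
#'   (um/px), e.g. from [gen_fiber_field()] or [read_fiber_tiff()].
#' @param min_length_um Minimum reported molecule length (um).
#' @param k_bg Threshold height in robust background SDs.
#' @param smooth_sigma Pre-threshold smoothing sigma (px).
#' @return List of traces, each with `id`, `polyline` ((x, y) pixel matrix)
#'   and `length_um`. Empty list for a blank field.
#' @export
trace_molecules <- function(field, min_length_um = 5, k_bg = 5,
                            smooth_sigma = 1) {
  img <- field$backbone
  px <- field$pixel_size
  if (diff(range(img)) <= 0) return(list())
  sm <- blur_sep(img, smooth_sigma)
  mask <- sm > median(sm) + k_bg * mad(sm)
  if (!any(mask)) return(list())
  skel <- thin_mask(mask)
  comps <- label8(skel)
  traces <- list()
  for (idx in comps) {
    if (length(idx) < 3L) next
    path <- longest_skeleton_path(idx, nrow(skel))
    if (length(path) < 2L) next
    rr <- (path - 1L) %% nrow(skel) + 1L
    cc <- (path - 1L) %/% nrow(skel) + 1L
    poly <- smooth_path(cbind(x = cc, y = rr))
    poly <- extend_to_mask(poly, mask)
    len <- polyline_length(poly) * px
    if (len < min_length_um) next
    traces[[length(traces) + 1L]] <- list(id = length(traces) + 1L,
                                          polyline = poly, length_um = len)
  }
  traces
}

# Separable Gaussian blur with zero padding; much cheaper than an FFT
# convolution at these kernel sizes.
blur_sep <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  # replicate-edge padding: zero padding would create spurious border
  # gradients (and band-pass maxima) wherever the background level is not 0
  pad <- img[c(rep(1L, r), 1:nr, rep(nr, r)), c(rep(1L, r), 1:nc, rep(nc, r))]
  out <- matrix(stats::filter(pad, k, sides = 2), nrow(pad))
  out <- t(matrix(stats::filter(t(out), k, sides = 2), ncol(pad)))
  out[(r + 1):(r + nr), (r + 1):(r + nc)]
}

# Thin each 4-connected mask component inside its bounding box; diagonal
# splits are rejoined later by the 8-connected skeleton labelling.
thin_mask <- function(mask) {
  lab <- matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask))
  skel <- matrix(FALSE, nrow(mask), ncol(mask))
  if (max(lab) == 0L) return(skel)
  px <- which(lab > 0L)
  ids <- lab[px]
  rr <- (px - 1L) %% nrow(mask) + 1L
  cc <- (px - 1L) %/% nrow(mask) + 1L
  rs <- split(rr, ids)
  cs <- split(cc, ids)
  for (k in seq_along(rs)) {
    r0 <- max(1L, min(rs[[k]]) - 1L); r1 <- min(nrow(mask), max(rs[[k]]) + 1L)
    c0 <- max(1L, min(cs[[k]]) - 1L); c1 <- min(ncol(mask), max(cs[[k]]) + 1L)
    sub <- lab[r0:r1, c0:c1] == k
    skel[r0:r1, c0:c1] <- skel[r0:r1, c0:c1] | thin_binary(sub)
  }
  skel
}

# Guo-Hall two-subiteration binary thinning, vectorized over the given
# mask. Chosen over Zhang-Suen, whose deletion rules remove 2-px diagonal
# staircases outright and so progressively shorten diagonal strokes.
thin_binary <- function(mask) {
  B <- mask
  nr <- nrow(B); nc <- ncol(B)
  shift <- function(M, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- M[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # x1..x8 clockwise from north (image convention: row = y)
      x1 <- shift(B, 1, 0); x2 <- shift(B, 1, -1); x3 <- shift(B, 0, -1)
      x4 <- shift(B, -1, -1); x5 <- shift(B, -1, 0); x6 <- shift(B, -1, 1)
      x7 <- shift(B, 0, 1); x8 <- shift(B, 1, 1)
      C <- (!x1 & (x2 | x3)) + (!x3 & (x4 | x5)) +
        (!x5 & (x6 | x7)) + (!x7 & (x8 | x1))
      n1 <- (x1 | x2) + (x3 | x4) + (x5 | x6) + (x7 | x8)
      n2 <- (x2 | x3) + (x4 | x5) + (x6 | x7) + (x8 | x1)
      nm <- pmin(n1, n2)
      o <- if (phase == 1) (x5 | x6 | !x8) & x7 else (x1 | x2 | !x4) & x3
      cond <- B & C == 1 & nm >= 2 & nm <= 3 & !o
      if (any(cond)) {
        B[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  B
}

# Moving-average smoothing of a pixel path (shrinking window at the ends).
# A raw 8-connected chain overestimates arc length by up to ~8% depending on
# orientation (staircase effect); averaging recovers the underlying line.
smooth_path <- function(poly, w = 5L) {
  n <- nrow(poly)
  if (n <= w) return(poly)
  half <- w %/% 2L
  cs <- rbind(c(0, 0), apply(poly, 2, cumsum))
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  cnt <- hi - lo
  cbind(x = (cs[hi + 1L, 1] - cs[lo + 1L, 1]) / cnt,
        y = (cs[hi + 1L, 2] - cs[lo + 1L, 2]) / cnt)
}

# The medial axis of a blunt stroke stops about half a line-width short of
# its tip; walk each path end outward along the local direction while still
# on foreground to recover the eroded ends.
extend_to_mask <- function(poly, mask, max_ext = 8L) {
  n <- nrow(poly)
  if (n < 4L) return(poly)
  one_end <- function(tip, inner) {
    d <- tip - inner
    d <- d / sqrt(sum(d^2))
    best <- 0L
    for (t in seq_len(max_ext)) {
      p <- tip + t * d
      r <- round(p[2]); c <- round(p[1])
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask) ||
          !mask[r, c]) break
      best <- t
    }
    if (best > 0L) tip + best * d else NULL
  }
  k <- min(4L, n - 1L)
  head_ext <- one_end(poly[1L, ], poly[1L + k, ])
  tail_ext <- one_end(poly[n, ], poly[n - k, ])
  rbind(head_ext, poly, tail_ext)
}

# 8-neighbour adjacency for a set of linear indices: row i holds the
# positions (within idx) of idx[i]'s neighbours, NA where absent.
adjacency8 <- function(idx, nr) {
  offs <- c(-1L - nr, -nr, 1L - nr, -1L, 1L, nr - 1L, nr, nr + 1L)
  adj <- matrix(NA_integer_, length(idx), 8L)
  for (k in 1:8) adj[, k] <- match(idx + offs[k], idx)
  adj
}

# 8-connected component labelling of a sparse logical mask; returns a list
# of linear-index vectors, one per component. (Needed because skeletons are
# 8-connected structures; 4-connected labelling splits diagonal runs.)
label8 <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  adj <- adjacency8(idx, nrow(mask))
  seen <- logical(length(idx))
  comps <- list()
  for (i in seq_along(idx)) {
    if (seen[i]) next
    queue <- integer(length(idx))
    queue[1L] <- i
    head <- 1L; tail <- 1L
    seen[i] <- TRUE
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[v, ]) {
        if (!is.na(w) && !seen[w]) {
          seen[w] <- TRUE
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    comps[[length(comps) + 1L]] <- idx[queue[seq_len(tail)]]
  }
  comps
}

# Longest path through a skeleton component (linear indices): BFS from an
# arbitrary pixel to the farthest one, then BFS again; the second far pixel
# and its parent chain give the component's diameter path.
longest_skeleton_path <- function(idx, nr) {
  n <- length(idx)
  adj <- adjacency8(idx, nr)
  bfs <- function(src) {
    parent <- rep(NA_integer_, n)
    dist <- rep(NA_integer_, n)
    dist[src] <- 0L
    queue <- integer(n)
    queue[1L] <- src
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[v, ]) {
        if (!is.na(w) && is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          parent[w] <- v
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
    list(parent = parent, dist = dist)
  }
  b1 <- bfs(1L)
  far1 <- which.max(b1$dist)
  b2 <- bfs(far1)
  far2 <- which.max(b2$dist)
  path <- integer(0)
  v <- far2
  while (!is.na(v)) {
    path <- c(path, v)
    v <- b2$parent[v]
  }
  idx[path]
}

#' Detect damage dots in the damage channel
#'
#' Band-passes the channel with a difference of Gaussians at the expected
#' point-spread sigma, finds local maxima above a noise-adaptive threshold
#' (`k` times the robust background SD of the band-passed image, estimated
#' by the median absolute deviation), and refines each detection to
#' sub-pixel precision by a 3x3 intensity centroid. Invariant to a constant
#' intensity offset.
#'
#' @param field Fiber field list with `damage` matrix.
#' @param psf_sigma Expected spot sigma in pixels.
#' @param k Detection threshold in robust background SDs.
#' @return Data.frame of dot coordinates (`x`, `y`, pixels, sub-pixel).
#' @export
detect_dots <- function(field, psf_sigma = 1.2, k = 5) {
  img <- field$damage
  if (diff(range(img)) <= 0) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  g1 <- blur_sep(img, psf_sigma)
  g2 <- blur_sep(img, 1.6 * psf_sigma)
  dog <- g1 - g2
  # robust background SD; strided subsample keeps the estimate cheap on
  # large frames without materially changing it
  thr <- k * mad(dog[seq(1L, length(dog), by = max(1L, length(dog) %/% 250000L))])
  nr <- nrow(dog); nc <- ncol(dog)
  core <- dog[2:(nr - 1), 2:(nc - 1)]
  is_max <- core > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    is_max <- is_max & core >= dog[2:(nr - 1) + dr, 2:(nc - 1) + dc]
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(data.frame(x = numeric(), y = numeric()))
  ry <- hits[, 1] + 1L
  cx <- hits[, 2] + 1L
  x <- numeric(nrow(hits)); y <- numeric(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    win <- dog[(ry[i] - 1):(ry[i] + 1), (cx[i] - 1):(cx[i] + 1)]
    w <- pmax(win - min(win), 0)
    x[i] <- cx[i] + sum(t(w) * (-1:1)) / sum(w)
    y[i] <- ry[i] + sum(w * (-1:1)) / sum(w)
  }
  data.frame(x = x, y = y)
}

#' Assign dots to traced molecules and quantify damage density
#'
#' Each dot is assigned to the nearest traced molecule within `max_dist`
#' pixels (point-to-polyline distance); farther dots are counted as
#' off-molecule background and excluded. Reports per-molecule dot counts and
#' densities and the pooled rate, defined as total dots over total length
#' (not the mean of per-molecule ratios). Dots/um converts to dots/Mbp via
#' the stretched-DNA constant of 3000 bp/um.
#'
#' Because two dots closer than the detector's resolution merge into one
#' detection, the raw pooled ratio undercounts at high density. The summary
#' therefore also reports a declumping-corrected pooled rate: modelling dot
#' positions along the fiber as a 1D Poisson process with intensity
#' `lambda`, detections are cluster leaders with density
#' `lambda * exp(-lambda * r)` at resolution distance `r`
#' (`resolve_dist` pixels); inverting this gives the corrected estimate.
#' The correction is negligible at sparse labeling and grows with density.
#'
#' @param traces Output of [trace_molecules()].
#' @param dots Data.frame of dot coordinates from [detect_dots()].
#' @param pixel_size um per pixel.
#' @param bp_per_um Conversion constant (bp per um; > 0).
#' @param max_dist Assignment radius in pixels.
#' @param resolve_dist Minimum separation (px) at which two dots are
#'   detected as two; used by the declumping correction.
#' @return A `damage_summary` list: `per_molecule` tibble (`dot_count`,
#'   `length_um`, `dots_per_um`, `dots_per_mbp`), `pooled_dots_per_um`,
#'   `pooled_dots_per_mbp` (total dots / total length),
#'   `pooled_dots_per_mbp_declumped`, `n_unassigned`, `bp_per_um`.
#' @export
assign_and_quantify <- function(traces, dots, pixel_size,
                                bp_per_um = 3000, max_dist = 3,
                                resolve_dist = 3) {
  if (bp_per_um <= 0) stop("bp_per_um must be > 0")
  n_tr <- length(traces)
  counts <- integer(n_tr)
  n_unassigned <- 0L
  if (n_tr > 0 && nrow(dots) > 0) {
    segs <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
      p <- traces[[i]]$polyline
      if (nrow(p) < 2) return(NULL)
      cbind(i, p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2])
    }))
    for (d in seq_len(nrow(dots))) {
      dist2 <- point_seg_dist2(dots$x[d], dots$y[d], segs)
      j <- which.min(dist2)
      if (sqrt(dist2[j]) <= max_dist) {
        counts[segs[j, 1]] <- counts[segs[j, 1]] + 1L
      } else {
        n_unassigned <- n_unassigned + 1L
      }
    }
  } else {
    n_unassigned <- nrow(dots)
  }
  len_um <- vapply(traces, `[[`, numeric(1), "length_um")
  per_mol <- tibble::tibble(
    molecule = seq_len(n_tr), dot_count = counts, length_um = len_um,
    dots_per_um = ifelse(len_um > 0, counts / len_um, NA_real_),
    dots_per_mbp = ifelse(len_um > 0,
                          counts / len_um / (bp_per_um * 1e-6), NA_real_))
  total_um <- sum(len_um)
  pooled_um <- if (total_um > 0) sum(counts) / total_um else NA_real_
  lambda_um <- declump_rate(pooled_um, resolve_dist * pixel_size)
  structure(list(per_molecule = per_mol,
                 pooled_dots_per_um = pooled_um,
                 pooled_dots_per_mbp = pooled_um / (bp_per_um * 1e-6),
                 pooled_dots_per_mbp_declumped = lambda_um / (bp_per_um * 1e-6),
                 total_length_um = total_um,
                 n_unassigned = n_unassigned,
                 bp_per_um = bp_per_um),
            class = "damage_summary")
}

# Invert mu = lambda * exp(-lambda * r) (observed cluster density ->
# underlying Poisson intensity, both per um; r in um) by fixed-point
# iteration on the sparse branch. At saturation (mu * r >= 1/e) the
# inversion is capped at 1/r.
declump_rate <- function(mu, r) {
  if (!is.finite(mu) || mu <= 0 || r <= 0) return(mu)
  if (mu * r >= exp(-1)) return(1 / r)
  lambda <- mu
  for (i in 1:50) {
    nxt <- mu * exp(lambda * r)
    if (abs(nxt - lambda) < 1e-12) break
    lambda <- nxt
  }
  lambda
}

# Squared distance from a point to segments given as columns
# (id, x1, y1, x2, y2); vectorized over segments.
point_seg_dist2 <- function(px, py, segs) {
  dx <- segs[, 4] - segs[, 2]
  dy <- segs[, 5] - segs[, 3]
  l2 <- dx * dx + dy * dy
  t <- ((px - segs[, 2]) * dx + (py - segs[, 3]) * dy) / pmax(l2, 1e-12)
  t <- pmin(pmax(t, 0), 1)
  qx <- segs[, 2] + t * dx
  qy <- segs[, 3] + t * dy
  (px - qx)^2 + (py - qy)^2
}

#' Compare pooled damage rates between conditions
#'
#' Takes per-replicate damage summaries grouped by condition, reports each
#' condition's mean and SD of the pooled dots/Mbp across replicates, and
#' compares every condition against the control with a two-sided two-sample
#' Welch t-test and a fold change. The declumping-corrected pooled rate is
#' used by default (see [assign_and_quantify()]); set `measure = "raw"` for
#' the uncorrected total-dots/total-length ratio. With identical
#' zero-variance replicate values in both groups the p-value is reported as
#' 1; with a single replicate per group the test is omitted with a warning.
#'
#' @param summaries Named list: one entry per condition, each a list of
#'   `damage_summary` objects (or bare numeric pooled dots/Mbp values).
#' @param control Name of the control condition.
#' @param measure Which pooled rate to compare.
#' @return Tibble with `condition`, `n_replicates`, `mean_dots_per_mbp`,
#'   `sd_dots_per_mbp`, `fold_vs_control`, `p_value`.
#' @export
summarize_conditions <- function(summaries, control = names(summaries)[1],
                                 measure = c("declumped", "raw")) {
  measure <- match.arg(measure)
  stopifnot(control %in% names(summaries))
  field <- if (measure == "declumped") "pooled_dots_per_mbp_declumped" else
    "pooled_dots_per_mbp"
  vals <- lapply(summaries, function(reps) {
    vapply(reps, function(r) {
      if (inherits(r, "damage_summary")) r[[field]] else as.numeric(r)
    }, numeric(1))
  })
  ctrl <- vals[[control]]
  rows <- lapply(names(vals), function(cn) {
    v <- vals[[cn]]
    p <- NA_real_
    if (cn != control) {
      if (length(v) < 2 || length(ctrl) < 2) {
        warning("single replicate in '", cn, "' or control; test omitted")
      } else if (sd(v) == 0 && sd(ctrl) == 0) {
        p <- if (isTRUE(all.equal(mean(v), mean(ctrl)))) 1 else 0
      } else {
        p <- t.test(v, ctrl)$p.value
      }
    }
    tibble::tibble(condition = cn, n_replicates = length(v),
                   mean_dots_per_mbp = mean(v),
                   sd_dots_per_mbp = if (length(v) > 1) sd(v) else NA_real_,
                   fold_vs_control = mean(v) / mean(ctrl),
                   p_value = p)
  })
  do.call(rbind, rows)
}
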