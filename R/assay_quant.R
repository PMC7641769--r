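#' Fiber tract-length statistics and group comparison
#'
#' Converts per-condition BrdU tract lengths from um to kb at the stretching
#' conversion (1 um of label ~ 2 kb), reports mean, standard error of the
#' mean and n per group, and compares every group against the control with
#' a two-sided Mann-Whitney U test (exact for small samples without ties,
#' normal approximation with tie correction otherwise, as `wilcox.test`
#' chooses).
#'
#' @param groups Named list of numeric um vectors, one per condition.
#' @param control Name of the control group.
#' @param kb_per_um Conversion factor (kb per um).
#' @return Tibble with `condition`, `n`, `mean_kb`, `sem_kb`,
#'   `p_vs_control` (NA for the control row).
#' @export
tract_stats <- function(groups, control = names(groups)[1], kb_per_um = 2) {
  stopifnot(length(groups) >= 2, control %in% names(groups))
  if (any(!vapply(groups, length, integer(1)))) {
    stop("empty tract-length group")
  }
  if (kb_per_um <= 0) stop("kb_per_um must be > 0")
  ctrl <- groups[[control]] * kb_per_um
  rows <- lapply(names(groups), function(cn) {
    x <- groups[[cn]] * kb_per_um
    p <- if (cn == control) NA_real_ else
      suppressWarnings(wilcox.test(x, ctrl)$p.value)
    tibble::tibble(condition = cn, n = length(x), mean_kb = mean(x),
                   sem_kb = sd(x) / sqrt(length(x)), p_vs_control = p)
  })
  do.call(rbind, rows)
}

#' Culture doubling time
#'
#' `t / log2(x / x0)` for a culture growing from density `x0` to `x` over
#' time `t` (hours).
#'
#' @param t Elapsed time in hours.
#' @param x0 Starting cell density (> 0).
#' @param x Ending cell density (> `x0` for a finite doubling time).
#' @param unit Output unit.
#' @return Doubling time in the requested unit.
#' @examples
#' doubling_time(12, 1e6, 4e6)            # 6 h
#' doubling_time(12, 1e6, 4e6, "minutes") # 360 min
#' @export
doubling_time <- function(t, x0, x, unit = c("hours", "minutes")) {
  unit <- match.arg(unit)
  if (any(t <= 0)) stop("t must be > 0")
  if (any(x0 <= 0)) stop("x0 must be > 0")
  if (any(x <= x0)) stop("no growth: x must exceed x0")
  dt <- t / log2(x / x0)
  if (unit == "minutes") dt * 60 else dt
}

#' Fraction of substrate unwound in a helicase assay
#'
#' `100 * P / (P + S)` where P is the pixel intensity of the unwound
#' (product) band and S the background-corrected intensity of the intact
#' substrate band.
#'
#' @param P Unwound-band intensity (>= 0).
#' @param S Intact-band intensity (>= 0); `P + S` must be positive.
#' @return Percentage in \[0, 100\].
#' @export
percent_unwound <- function(P, S) {
  if (any(P < 0) || any(S < 0)) stop("band intensities must be >= 0")
  if (any(P + S <= 0)) stop("P + S must be > 0")
  100 * P / (P + S)
}

#' Molar ellipticity from a CD spectrum
#'
#' Normalizes measured millidegree ellipticities to molar ellipticity:
#' `[theta] = m_deg * M / (10 * L * C)` with molecular weight `M` (g/mol),
#' path length `L` (cm) and concentration `C` (g/l). Linear in `m_deg` and
#' inverse in `C`.
#'
#' @param m_deg Millidegree readings (vectorized over wavelengths).
#' @param M Molecular weight, g/mol (> 0).
#' @param L Cuvette path length, cm (> 0).
#' @param C Concentration, g/l (> 0).
#' @return Molar ellipticity values, same length as `m_deg`.
#' @export
molar_ellipticity <- function(m_deg, M, L, C) {
  if (M <= 0 || L <= 0 || C <= 0) stop("M, L and C must be > 0")
  m_deg * M / (10 * L * C)
}

#' Relative DNA amplification from qPCR-stop Cq values
#'
#' Standard double-delta quantification for the qPCR stop assay: for each
#' target, `dCq = Cq(condition) - Cq(control condition)`; the G4 target's
#' dCq is referenced against a non-G4 reference target
#' (`ddCq = dCq(target) - dCq(reference)`), and relative amplification is
#' `2^-ddCq`. Replicate Cq values within a (target, condition) cell are
#' averaged first.
#'
#' @param measurements Data.frame with columns `target`, `condition`, `cq`.
#' @param reference_target Non-quadruplex reference target (e.g. `ade6`).
#' @param control_condition Baseline condition (e.g. no-KCl/DMSO).
#' @return Tibble with `target`, `condition`, `d_cq`, `dd_cq`,
#'   `relative_amplification` for every non-reference target.
#' @export
relative_amplification <- function(measurements, reference_target,
                                   control_condition) {
  m <- as.data.frame(measurements)
  stopifnot(all(c("target", "condition", "cq") %in% names(m)))
  if (any(m$cq <= 0)) stop("Cq values must be > 0")
  if (!reference_target %in% m$target) {
    stop("reference target '", reference_target, "' missing from measurements")
  }
  if (!control_condition %in% m$condition) {
    stop("control condition '", control_condition,
         "' missing from measurements")
  }
  cell <- function(tg, cn) {
    v <- m$cq[m$target == tg & m$condition == cn]
    if (!length(v)) {
      stop(sprintf("missing Cq for target '%s' in condition '%s'", tg, cn))
    }
    mean(v)
  }
  targets <- setdiff(unique(m$target), reference_target)
  conds <- unique(m$condition)
  rows <- list()
  for (tg in targets) {
    for (cn in conds) {
      d_t <- cell(tg, cn) - cell(tg, control_condition)
      d_r <- cell(reference_target, cn) - cell(reference_target,
                                               control_condition)
      dd <- d_t - d_r
      rows[[length(rows) + 1L]] <- tibble::tibble(
        target = tg, condition = cn, d_cq = d_t, dd_cq = dd,
        relative_amplification = 2^(-dd))
    }
  }
  do.call(rbind, rows)
}
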