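#' Total base pairs covered by a set of intervals
#'
#' Length of the union of the intervals (overlapping bases counted once),
#' the "Tot bp covered" accounting used when comparing conditions whose peak
#' numbers differ. Permutation-invariant.
#'
#' @param intervals A `GRanges`, or a data.frame with `seqname` (optional),
#'   `start`, `end` in 0-based half-open coordinates.
#' @return Integer bp count.
#' @export
union_bp <- function(intervals) {
  gr <- as_granges0(intervals)
  if (length(gr) == 0L) return(0L)
  sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
}

# Coerce 0-based half-open tabular intervals (or a GRanges) to GRanges.
as_granges0 <- function(x, keep_mcols = TRUE) {
  if (inherits(x, "GRanges")) return(x)
  x <- as.data.frame(x)
  if (nrow(x) == 0L) return(GenomicRanges::GRanges())
  if (any(x$start < 0)) stop("negative start coordinate")
  if (any(x$start >= x$end)) stop("interval with start >= end")
  sn <- if ("seqname" %in% names(x)) x$seqname else "seq"
  gr <- GenomicRanges::GRanges(
    seqnames = sn,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*")
  if (keep_mcols && "score" %in% names(x)) gr$score <- x$score
  if (keep_mcols && "name" %in% names(x)) gr$name <- x$name
  gr
}

#' Overlap counts between peaks and a feature class
#'
#' A peak counts once if it overlaps at least one feature by >= 1 bp, and a
#' feature counts once if it overlaps at least one peak -- the two directions
#' of the Table-2-style accounting ("peaks with G4" vs "G4 within peaks").
#' Strand-agnostic; "within" means any overlap, not full containment.
#'
#' @param peaks,features Interval sets (`GRanges` or 0-based data.frames).
#' @return Named integer vector `c(peaks_with_feature, features_within_peaks)`.
#' @export
overlap_counts <- function(peaks, features) {
  p <- as_granges0(peaks)
  f <- as_granges0(features)
  GenomicRanges::strand(p) <- "*"
  GenomicRanges::strand(f) <- "*"
  c(peaks_with_feature = sum(IRanges::overlapsAny(p, f)),
    features_within_peaks = sum(IRanges::overlapsAny(f, p)))
}

#' GC content of the genomic bases under a peak set
#'
#' Computed over the union of the peaks (overlapping bases counted once);
#' N bases are excluded from the denominator.
#'
#' @param peaks Interval set.
#' @param genome A `DNAStringSet` (or path to a FASTA file).
#' @return Percentage, rounded half-away-from-zero to 1 decimal.
#' @export
gc_percent <- function(peaks, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- GenomicRanges::reduce(as_granges0(peaks))
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(gr)) {
    sn <- as.character(GenomicRanges::seqnames(gr)[i])
    if (!sn %in% names(genome)) stop("peak on unknown sequence: ", sn)
    s <- GenomicRanges::start(gr)[i]
    e <- GenomicRanges::end(gr)[i]
    if (s < 1L || e > length(genome[[sn]])) {
      stop("peak outside genome bounds on ", sn)
    }
    fr <- Biostrings::letterFrequency(genome[[sn]][s:e], c("A", "C", "G", "T"))
    counts <- counts + as.numeric(fr)
  }
  denom <- sum(counts)
  if (denom == 0) stop("no unambiguous bases under peaks")
  round_half_up(100 * (counts[["C"]] + counts[["G"]]) / denom, 1)
}

#' Between-condition fold change
#'
#' Ratio treated/mock. The unrounded value is returned; reports round
#' half-away-from-zero to 2 decimals with trailing zeros trimmed (so 6/5
#' prints "1.2" and 16/7 prints "2.29").
#'
#' @param treated Non-negative numerator.
#' @param mock Positive denominator.
#' @return Numeric fold change (unrounded), with the printed representation
#'   available via `attr(, "printed")`.
#' @export
fold_change <- function(treated, mock) {
  if (any(mock <= 0)) stop("mock value must be > 0")
  if (any(treated < 0)) stop("treated value must be >= 0")
  structure(treated / mock, printed = format_fold(treated / mock))
}

#' Assemble the per-condition enrichment ledger
#'
#' Fills the Table-2-shaped accounting for a mock and a treated peak set:
#' peak number, union bp coverage, mean peak length (rounded to bp), GC
#' percentage (when a genome is supplied), both overlap counts per feature
#' class, and treated/mock fold changes for bp coverage and for the
#' features-within-peaks count of every class.
#'
#' @param mock,treated Peak sets (`GRanges` or 0-based data.frames).
#' @param feature_sets Named list of feature interval sets (e.g.
#'   `list(g4 = ..., trna = ..., rrna5s = ...)`).
#' @param genome Optional `DNAStringSet`/FASTA path for the GC column.
#' @return An `enrichment_ledger`: list with `conditions` (tibble, one row
#'   per condition) and `fold_changes` (tibble with unrounded `value` and
#'   `printed` columns).
#' @export
build_ledger <- function(mock, treated, feature_sets = list(), genome = NULL) {
  stopifnot(is.list(feature_sets))
  cond <- list(mock = mock, treated = treated)
  rows <- lapply(names(cond), function(cn) {
    p <- as_granges0(cond[[cn]])
    bp <- union_bp(p)
    r <- tibble::tibble(
      condition = cn, n_peaks = length(p), total_bp_covered = bp,
      mean_peak_length = as.integer(round_half_up(bp / length(p))),
      gc_percent = if (is.null(genome)) NA_real_ else gc_percent(p, genome))
    for (fn in names(feature_sets)) {
      oc <- overlap_counts(p, feature_sets[[fn]])
      r[[paste0("peaks_with_", fn)]] <- oc[["peaks_with_feature"]]
      r[[paste0(fn, "_within_peaks")]] <- oc[["features_within_peaks"]]
    }
    r
  })
  conditions <- do.call(rbind, rows)
  ledger_from_conditions(conditions, names(feature_sets))
}

# Shared fold-change assembly for build_ledger() and ledger_from_counts().
ledger_from_conditions <- function(conditions, feature_names) {
  m <- conditions[conditions$condition == "mock", ]
  t <- conditions[conditions$condition == "treated", ]
  qty <- c("total_bp_covered", paste0(feature_names, "_within_peaks"))
  lab <- c("bp_covered", feature_names)
  fc <- tibble::tibble(
    quantity = lab,
    value = unname(vapply(qty, function(q) t[[q]] / m[[q]], numeric(1))),
    printed = unname(vapply(qty, function(q) format_fold(t[[q]] / m[[q]]),
                            character(1))))
  structure(list(conditions = conditions, fold_changes = fc),
            class = "enrichment_ledger")
}

#' Enrichment ledger from pre-tabulated counts
#'
#' Builds the same ledger object as [build_ledger()] directly from published
#' per-condition counts (peak number, union bp coverage and
#' features-within-peaks counts per class), for re-deriving the fold-change
#' and mean-length columns of a printed table.
#'
#' @param n_peaks,bp_covered Length-2 numeric vectors, `c(mock, treated)`.
#' @param feature_counts Named list of length-2 vectors `c(mock, treated)`
#'   of features-within-peaks counts.
#' @param gc Optional length-2 vector of GC percentages.
#' @return An `enrichment_ledger`.
#' @export
ledger_from_counts <- function(n_peaks, bp_covered, feature_counts = list(),
                               gc = c(NA_real_, NA_real_)) {
  conditions <- tibble::tibble(
    condition = c("mock", "treated"),
    n_peaks = as.integer(n_peaks),
    total_bp_covered = as.numeric(bp_covered),
    mean_peak_length = as.integer(round_half_up(bp_covered / n_peaks)),
    gc_percent = as.numeric(gc))
  for (fn in names(feature_counts)) {
    conditions[[paste0(fn, "_within_peaks")]] <- feature_counts[[fn]]
  }
  ledger_from_conditions(conditions, names(feature_counts))
}

#' @export
print.enrichment_ledger <- function(x, ...) {
  cat("Enrichment ledger (treated vs mock)\n")
  print(x$conditions)
  cat("\nFold changes:\n")
  for (i in seq_len(nrow(x$fold_changes))) {
    cat(sprintf("  %-12s %s\n", x$fold_changes$quantity[i],
                x$fold_changes$printed[i]))
  }
  invisible(x)
}

#' Select the n best-scoring peaks
#'
#' Higher score is better; ties are broken by (sequence name, start) so the
#' selection is deterministic. Used, e.g., to focus on the 100 most
#' consistent peaks of a condition.
#'
#' @param peaks Peak set with a `score` column/metadata.
#' @param n Number of peaks to keep.
#' @return Peak set of the same class as the input subset.
#' @export
top_n_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  gr <- as_granges0(peaks)
  sc <- gr$score
  if (is.null(sc) || anyNA(sc)) stop("peaks must carry scores")
  if (n > length(gr)) {
    warning("n exceeds the number of peaks; returning all ", length(gr))
    n <- length(gr)
  }
  ord <- order(-sc, as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr))
  sel <- gr[sort(ord[seq_len(n)])]
  if (inherits(peaks, "GRanges")) sel else granges_to_df0(sel)
}

# GRanges back to a 0-based half-open data.frame.
granges_to_df0 <- function(gr) {
  df <- data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  for (nm in colnames(mc)) df[[nm]] <- mc[[nm]]
  st <- as.character(GenomicRanges::strand(gr))
  if (!all(st == "*")) df$strand <- st
  df
}

#' Pseudo-replicate reproducibility ratio (Np/Nt)
#'
#' Compares the number of reproducible peaks called from pooled-and-split
#' pseudo-replicates (Np) against the number from the true biological
#' replicates (Nt). An Np within a factor of 2 of Nt (0.5 <= Np/Nt <= 2)
#' indicates reliable replicates.
#'
#' @param n_true Nt, peaks from true replicates (> 0).
#' @param n_pseudo Np, peaks from pseudo-replicates.
#' @return List with `n_true`, `n_pseudo`, `ratio` (rounded to 2 decimals)
#'   and the `reliable` flag.
#' @export
reproducibility_ratio <- function(n_true, n_pseudo) {
  if (n_true <= 0) stop("n_true must be > 0")
  r <- n_pseudo / n_true
  list(n_true = n_true, n_pseudo = n_pseudo,
       ratio = round_half_up(r, 2),
       reliable = r >= 0.5 && r <= 2)
}
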