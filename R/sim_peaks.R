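#' Generate a random feature annotation
#'
#' Uniformly placed, non-overlapping fixed-width features (e.g. a G4 motif
#' annotation) over the peak coordinate space, for use with
#' [gen_peak_experiment()].
#'
#' @param config A [sim_config()].
#' @param n Number of features.
#' @param width Feature width (bp).
#' @return 0-based half-open data.frame (`seqname`, `start`, `end`).
#' @export
gen_features <- function(config = sim_config(), n = 446L, width = 30L) {
  with_config_seed(config, 2L, {
    G <- config$peak_genome_length
    start <- sort(sample.int(G - width, n))
    # enforce non-overlap by nudging right where needed
    for (i in seq_len(n)[-1]) {
      if (start[i] < start[i - 1] + width) start[i] <- start[i - 1] + width
    }
    if (start[n] + width > G) stop("features do not fit in peak space")
    data.frame(seqname = "chrS", start = start, end = start + width,
               stringsAsFactors = FALSE)
  })
}

#' Generate a two-condition, two-replicate scored peak experiment
#'
#' Emulates the design of a duplicate ChIP-seq experiment under a mock and a
#' treated condition. Each condition has `n_peaks_per_replicate` true peaks;
#' a peak is deliberately centered on a feature with probability given by
#' the configured odds (`feature_base_odds`, multiplied by
#' `feature_enrichment` for the treated condition). Deliberate placements
#' sample features without replacement, and off-feature placements avoid
#' features, so the planted odds are exact and the configured enrichment is
#' recoverable from the ledger. Each replicate keeps a
#' `replicate_shared_fraction` of the condition's true peaks and fills the
#' remainder with non-reproducible background peaks. Scores are 0--1000 and
#' decrease with the placement noise of the peak center.
#'
#' @param config A [sim_config()].
#' @param features Feature set (0-based data.frame or `GRanges`).
#' @return List with `peaks` (`$mock`/`$treated`, each `$rep1`/`$rep2`
#'   scored 0-based data.frames), and `truth` (true per-condition peak
#'   tables with an `on_feature` flag, plus the configured odds).
#' @export
gen_peak_experiment <- function(config = sim_config(), features) {
  feats <- granges_to_df0(as_granges0(features))
  if (nrow(feats) == 0L && config$feature_enrichment > 1) {
    stop("empty feature set with feature_enrichment > 1")
  }
  if (nrow(feats) > 0 && max(feats$end) > config$peak_genome_length) {
    stop("features do not fit within peak_genome_length")
  }
  with_config_seed(config, 3L, {
    odds <- c(mock = config$feature_base_odds,
              treated = config$feature_base_odds * config$feature_enrichment)
    out_peaks <- list()
    out_truth <- list()
    for (cn in c("mock", "treated")) {
      p_on <- odds[[cn]] / (1 + odds[[cn]])
      tr <- draw_true_peaks(config, feats, p_on)
      out_truth[[cn]] <- tr
      n <- config$n_peaks_per_replicate
      n_shared <- round(config$replicate_shared_fraction * n)
      shared_idx <- if (n_shared > 0) sample.int(n, n_shared) else integer()
      reps <- list()
      for (rn in c("rep1", "rep2")) {
        extra <- draw_background_peaks(config, n - n_shared)
        rp <- rbind(tr[sort(shared_idx),
                       c("seqname", "start", "end", "score")], extra)
        rp <- rp[order(rp$seqname, rp$start), ]
        rownames(rp) <- NULL
        reps[[rn]] <- rp
      }
      out_peaks[[cn]] <- reps
    }
    list(peaks = out_peaks,
         truth = list(true_peaks = out_truth, odds = odds))
  })
}

# n_peaks_per_replicate true peaks for one condition; deliberate on-feature
# placements pick distinct features, off-feature placements reject feature
# overlap. Placement noise shifts the center and sets the score.
draw_true_peaks <- function(config, feats, p_on) {
  n <- config$n_peaks_per_replicate
  G <- config$peak_genome_length
  on_feat <- runif(n) < p_on
  if (sum(on_feat) > nrow(feats)) {
    stop("not enough features for the requested on-feature placements")
  }
  len <- pmax(50, round(rnorm(n, config$peak_length_mean,
                              config$peak_length_sd)))
  noise <- rnorm(n, 0, 150)
  center <- numeric(n)
  chosen <- if (any(on_feat)) sample.int(nrow(feats), sum(on_feat)) else
    integer()
  center[on_feat] <- (feats$start[chosen] + feats$end[chosen]) / 2 +
    noise[on_feat]
  for (i in which(!on_feat)) {
    repeat {
      c0 <- runif(1, 1, G)
      s <- max(0, round(c0 - len[i] / 2))
      e <- s + len[i]
      if (!any(s < feats$end & e > feats$start)) break
    }
    center[i] <- c0
  }
  start <- pmax(0, round(center - len / 2))
  end <- pmin(G, start + len)
  score <- round(1000 * exp(-abs(noise) / 500))
  df <- data.frame(seqname = "chrS", start = as.integer(start),
                   end = as.integer(end), score = as.numeric(score),
                   on_feature = on_feat, stringsAsFactors = FALSE)
  df[order(df$start), , drop = FALSE]
}

# Non-reproducible replicate-specific background peaks (uniform, low score).
draw_background_peaks <- function(config, n) {
  if (n == 0L) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  G <- config$peak_genome_length
  len <- pmax(50, round(rnorm(n, config$peak_length_mean,
                              config$peak_length_sd)))
  start <- pmax(0, round(runif(n, 1, G) - len / 2))
  data.frame(seqname = "chrS", start = as.integer(start),
             end = as.integer(pmin(G, start + len)),
             score = round(runif(n, 50, 400)), stringsAsFactors = FALSE)
}
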