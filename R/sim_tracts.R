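#' Generate fiber tract-length samples for two conditions
#'
#' Draws per-condition BrdU tract lengths from a normal distribution in kb
#' truncated at zero (negative draws re-drawn) and converts them to um at
#' the stretching conversion of 2 kb per um. Defaults reproduce the study
#' design: n = 17 control vs n = 50 treated fibers, 60 vs 40 kb means
#' (a one-third reduction), SD 15 kb.
#'
#' @param config A [sim_config()].
#' @return List with `samples_um` (named list of um vectors per condition)
#'   and `truth` (the generating kb parameters and `kb_per_um`).
#' @export
gen_tract_sample <- function(config = sim_config()) {
  with_config_seed(config, 5L, {
    conds <- names(config$tract_mean)
    samples <- lapply(conds, function(cn) {
      x <- rtrunc_norm(config$tract_n[[cn]], config$tract_mean[[cn]],
                       config$tract_sd[[cn]])
      x / config$kb_per_um
    })
    names(samples) <- conds
    list(samples_um = samples,
         truth = list(mean_kb = config$tract_mean, sd_kb = config$tract_sd,
                      n = config$tract_n, kb_per_um = config$kb_per_um))
  })
}

# Zero-truncated normal by rejection; degenerate sd = 0 returns the mean.
rtrunc_norm <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}
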