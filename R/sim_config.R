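#' Configuration for the synthetic-data generators
#'
#' One configuration object drives all four generators (genome, peak
#' experiment, fiber field, tract sample). Identical configurations --
#' including the seed -- give identical outputs. Defaults reflect the study
#' design being emulated: a fission-yeast-sized peak space, a two-condition
#' by two-replicate peak experiment, stretched-DNA fields imaged at
#' 0.16 um/px, a planted damage rate of 30 dots/Mbp with a 3-fold treated
#' increase, and fiber tract samples of n = 17 (control) vs n = 50 (treated)
#' with a one-third mean reduction.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param genome_length Length (bp) of generated genomes.
#' @param gc_fraction Background GC fraction in \[0, 1\].
#' @param n_planted_motifs Number of G4 motifs planted (half per strand).
#' @param tract_length_range,loop_length_range Ranges (bp) for planted
#'   G-tract and loop lengths.
#' @param peak_genome_length Coordinate space (bp) for the peak experiment.
#' @param n_peaks_per_replicate Peaks per replicate.
#' @param peak_length_mean,peak_length_sd Peak length distribution (bp).
#' @param feature_base_odds Odds that a mock-condition true peak is centered
#'   on a feature.
#' @param feature_enrichment Multiplier on those odds for the treated
#'   condition.
#' @param replicate_shared_fraction Fraction of true peaks shared by the two
#'   replicates of a condition.
#' @param n_molecules Molecules per fiber field.
#' @param molecule_length_mean,molecule_length_sd Molecule length (um).
#' @param min_molecule_length Shortest molecule reported by tracing (um).
#' @param damage_rate Planted damage density, dots per Mbp.
#' @param damage_fold_treated Multiplier on `damage_rate` for the treated
#'   condition.
#' @param pixel_size Image scale, um per pixel.
#' @param psf_sigma Point-spread-function sigma, pixels.
#' @param background_noise_sd Gaussian background noise SD, intensity counts.
#' @param background_level Mean background level, counts.
#' @param snr Peak signal amplitude over `background_noise_sd`.
#' @param image_size Field edge length, pixels (square frames).
#' @param tract_mean,tract_sd,tract_n Named per-condition tract-length
#'   parameters: means/SDs in kb and sample sizes.
#' @param kb_per_um Fiber stretching conversion (2 kb per um of BrdU label).
#' @param bp_per_um Stretched-molecule conversion for damage imaging
#'   (3000 bp per um).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       gc_fraction = 0.36,
                       n_planted_motifs = 20L,
                       tract_length_range = c(3L, 5L),
                       loop_length_range = c(1L, 12L),
                       peak_genome_length = 12.5e6,
                       n_peaks_per_replicate = 400L,
                       peak_length_mean = 1000,
                       peak_length_sd = 200,
                       feature_base_odds = 0.05,
                       feature_enrichment = 2,
                       replicate_shared_fraction = 0.8,
                       n_molecules = 200L,
                       molecule_length_mean = 15,
                       molecule_length_sd = 5,
                       min_molecule_length = 5,
                       damage_rate = 30,
                       damage_fold_treated = 3,
                       pixel_size = 0.16,
                       psf_sigma = 1.2,
                       background_noise_sd = 50,
                       background_level = 500,
                       snr = 5,
                       image_size = 2048L,
                       tract_mean = c(control = 60, treated = 40),
                       tract_sd = c(control = 15, treated = 15),
                       tract_n = c(control = 17L, treated = 50L),
                       kb_per_um = 2,
                       bp_per_um = 3000) {
  cfg <- list(seed = as.integer(seed), genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              n_planted_motifs = as.integer(n_planted_motifs),
              tract_length_range = as.integer(tract_length_range),
              loop_length_range = as.integer(loop_length_range),
              peak_genome_length = peak_genome_length,
              n_peaks_per_replicate = as.integer(n_peaks_per_replicate),
              peak_length_mean = peak_length_mean,
              peak_length_sd = peak_length_sd,
              feature_base_odds = feature_base_odds,
              feature_enrichment = feature_enrichment,
              replicate_shared_fraction = replicate_shared_fraction,
              n_molecules = as.integer(n_molecules),
              molecule_length_mean = molecule_length_mean,
              molecule_length_sd = molecule_length_sd,
              min_molecule_length = min_molecule_length,
              damage_rate = damage_rate,
              damage_fold_treated = damage_fold_treated,
              pixel_size = pixel_size, psf_sigma = psf_sigma,
              background_noise_sd = background_noise_sd,
              background_level = background_level, snr = snr,
              image_size = as.integer(image_size),
              tract_mean = tract_mean, tract_sd = tract_sd,
              tract_n = tract_n, kb_per_um = kb_per_um,
              bp_per_um = bp_per_um)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("genome_length", "peak_genome_length", "n_peaks_per_replicate",
           "peak_length_mean", "peak_length_sd", "n_molecules",
           "molecule_length_mean", "molecule_length_sd", "min_molecule_length",
           "pixel_size", "psf_sigma", "background_noise_sd", "snr",
           "image_size", "kb_per_um", "bp_per_um", "feature_enrichment",
           "feature_base_odds", "damage_fold_treated")
  for (nm in pos) {
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0)) {
      stop("sim_config: ", nm, " must be strictly positive")
    }
  }
  for (nm in c("gc_fraction", "replicate_shared_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop("sim_config: ", nm, " must be in [0, 1]")
    }
  }
  if (cfg$n_planted_motifs < 0) stop("sim_config: n_planted_motifs < 0")
  if (cfg$damage_rate < 0) stop("sim_config: damage_rate must be >= 0")
  if (any(cfg$tract_length_range < 2L) ||
      cfg$tract_length_range[1] > cfg$tract_length_range[2]) {
    stop("sim_config: invalid tract_length_range")
  }
  if (cfg$loop_length_range[1] < 1L ||
      cfg$loop_length_range[1] > cfg$loop_length_range[2] ||
      cfg$loop_length_range[2] > 25L) {
    stop("sim_config: loop_length_range must lie within [1, 25]")
  }
  if (any(cfg$tract_mean <= 0) || any(cfg$tract_sd < 0) ||
      any(cfg$tract_n < 1)) {
    stop("sim_config: invalid tract sample parameters")
  }
  invisible(cfg)
}

# Scoped RNG: every generator runs under the config seed (plus a stream
# offset) and restores the caller's RNG state afterwards.
with_config_seed <- function(cfg, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((cfg$seed + 97L * stream) %% .Machine$integer.max)
  force(code)
}
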