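#' Simulation parameters for the synthetic study generator
#'
#' Collects every tunable of the synthetic-data module in one validated
#' object. Defaults describe a desk-scale version of the emulated study: a
#' few hundred proteins quantified by spectral counting at a sequencing-like
#' depth of ~20,000 PSM per sample, ~50 metabolites, a handful of
#' physiological variables, planted time responders with up to `effect_size`
#' fold change, correlated protein/metabolite/physiology blocks driven by
#' shared latent factors, deterministic detection dropout, MCAR missingness
#' in the metabolome, and standalone lag-1 causal series pairs.
#'
#' @param n_proteins,n_metabolites,n_physio Feature counts per block.
#' @param length_range Integer interval (min, max) for protein lengths in
#'   amino-acid residues.
#' @param depth Expected total PSM count per sample.
#' @param effect_size Maximal fold change of planted responder profiles
#'   (must be > 1 for responders to be detectable).
#' @param responder_frac Fraction of proteins given a planted time profile.
#' @param n_factors Number of shared latent factors driving correlated
#'   blocks.
#' @param factor_loading Correlation of block features to their latent
#'   factor, in (0, 1].
#' @param block_proteins,block_metabolites Number of proteins/metabolites
#'   assigned to each latent factor.
#' @param dropout_threshold Expected-count level below which a protein is
#'   recorded as undetected (0) in that sample; dropout is deterministic.
#' @param missing_rate Fraction of metabolite cells blanked completely at
#'   random, in [0, 1).
#' @param noise_sd Replicate-to-replicate log-scale noise SD for features
#'   outside latent-factor blocks.
#' @param baseline_sdlog Log-scale SD of protein/metabolite baseline
#'   abundances.
#' @param factor_noise_sd SD of the sample-level (replicate) component of
#'   each latent factor, relative to a unit-amplitude time profile.
#' @param physio_noise_sd Measurement noise SD of physiology variables,
#'   relative to a unit factor score.
#' @param series_length Length T of the standalone causal series (>= 10).
#' @param n_causal_pairs,n_null_series Counts of planted lag-1 causal pairs
#'   and of additional independent white-noise series.
#' @param causal_beta Lag-1 coefficient of planted causal pairs.
#' @param causal_noise_sd Innovation SD of causal target series.
#' @param count_law `"poisson"` draws observed PSM as Poisson counts around
#'   the length-weighted expectation; `"expected"` returns the expectation
#'   itself (used for exact-recovery checks).
#' @param seed Default base seed used when a simulator is called without an
#'   explicit seed.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 500L,
                       n_metabolites = 50L,
                       n_physio = 5L,
                       length_range = c(100L, 1500L),
                       depth = 20000,
                       effect_size = 6,
                       responder_frac = 0.2,
                       n_factors = 3L,
                       factor_loading = 0.9,
                       block_proteins = 6L,
                       block_metabolites = 4L,
                       dropout_threshold = 0.5,
                       missing_rate = 0.05,
                       noise_sd = 0.2,
                       baseline_sdlog = 1,
                       factor_noise_sd = 0.5,
                       physio_noise_sd = 0.1,
                       series_length = 50L,
                       n_causal_pairs = 5L,
                       n_null_series = 10L,
                       causal_beta = 0.9,
                       causal_noise_sd = 0.1,
                       count_law = c("poisson", "expected"),
                       seed = 1L) {
  count_law <- match.arg(count_law)
  p <- list(
    n_proteins = as.integer(n_proteins),
    n_metabolites = as.integer(n_metabolites),
    n_physio = as.integer(n_physio),
    length_range = as.integer(length_range),
    depth = as.numeric(depth),
    effect_size = as.numeric(effect_size),
    responder_frac = as.numeric(responder_frac),
    n_factors = as.integer(n_factors),
    factor_loading = as.numeric(factor_loading),
    block_proteins = as.integer(block_proteins),
    block_metabolites = as.integer(block_metabolites),
    dropout_threshold = as.numeric(dropout_threshold),
    missing_rate = as.numeric(missing_rate),
    noise_sd = as.numeric(noise_sd),
    baseline_sdlog = as.numeric(baseline_sdlog),
    factor_noise_sd = as.numeric(factor_noise_sd),
    physio_noise_sd = as.numeric(physio_noise_sd),
    series_length = as.integer(series_length),
    n_causal_pairs = as.integer(n_causal_pairs),
    n_null_series = as.integer(n_null_series),
    causal_beta = as.numeric(causal_beta),
    causal_noise_sd = as.numeric(causal_noise_sd),
    count_law = count_law,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

#' @keywords internal
validate_sim_params <- function(p) {
  pos <- c("n_proteins", "depth", "effect_size", "n_factors",
           "baseline_sdlog", "series_length")
  for (f in pos) {
    if (!is.finite(p[[f]]) || p[[f]] <= 0) {
      stop("parameter error: `", f, "` must be positive", call. = FALSE)
    }
  }
  nonneg <- c("n_metabolites", "n_physio", "responder_frac", "dropout_threshold",
              "noise_sd", "factor_noise_sd", "physio_noise_sd",
              "n_causal_pairs", "n_null_series", "causal_noise_sd")
  for (f in nonneg) {
    if (!is.finite(p[[f]]) || p[[f]] < 0) {
      stop("parameter error: `", f, "` must be non-negative", call. = FALSE)
    }
  }
  if (p$missing_rate < 0 || p$missing_rate >= 1) {
    stop("parameter error: `missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (p$factor_loading <= 0 || p$factor_loading > 1) {
    stop("parameter error: `factor_loading` must lie in (0, 1]", call. = FALSE)
  }
  if (length(p$length_range) != 2L || p$length_range[1] < 1L ||
      p$length_range[2] < p$length_range[1]) {
    stop("parameter error: `length_range` must be an increasing positive interval",
         call. = FALSE)
  }
  invisible(TRUE)
}
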