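#' Latent-factor time profiles
#'
#' Deterministic per-timepoint means of the shared latent factors. For the
#' default six-timepoint design the first three factors encode the
#' biologically motivated shapes the generator emulates: a starvation
#' response peaking late in starvation, a recovery/growth response rising
#' only after replenishment, and an early transient. Additional factors (or
#' non-default designs) fall back to phase-shifted sinusoids over the
#' timepoint rank so any design gets distinct smooth profiles.
#'
#' @param timepoints Numeric vector of sampling times.
#' @param n_factors Number of factors.
#' @return Matrix `length(timepoints) x n_factors`.
#' @keywords internal
factor_profiles <- function(timepoints, n_factors) {
  nt <- length(timepoints)
  ## starvation state builds during depletion and persists shortly after
  ## replenishment (5 h post-readdition samples still resemble starved
  ## cells); fully recovered samples return near the control state
  canonical <- list(
    starvation = c(0, 0.3, 2.0, 2.2, 1.8, 0.1),
    recovery   = c(0.3, 0, -0.6, -1.0, 1.5, 0.6),
    transient  = c(0, 2.0, 0.8, 0.2, 1.6, 0.3)
  )
  prof <- matrix(0, nt, n_factors)
  for (f in seq_len(n_factors)) {
    if (nt == 6L && f <= 3L) {
      prof[, f] <- canonical[[f]]
    } else {
      r <- seq_len(nt) - 1L
      prof[, f] <- 1.5 * sin(pi * (f * r / max(nt - 1L, 1L) + (f - 1) / 4))
    }
  }
  rownames(prof) <- as.character(timepoints)
  prof
}

#' Draw standardized latent-factor scores for every sample
#'
#' Each factor score is its deterministic time profile plus an independent
#' per-sample (replicate-level) Gaussian component, standardized to mean 0
#' and unit SD across samples. Features of the same block share the whole
#' score, including the replicate component; only their private noise is
#' independent.
#'
#' @param design Sample table from [generate_design()].
#' @param n_factors Number of factors.
#' @param factor_noise_sd SD of the replicate-level component.
#' @param seed Integer seed.
#' @return Matrix `n_samples x n_factors` with samples in design order.
#' @export
simulate_factor_scores <- function(design, n_factors, factor_noise_sd = 0.5,
                                   seed = 1L) {
  set.seed(seed)
  prof <- factor_profiles(sort(unique(design$timepoint)), n_factors)
  z <- prof[as.character(design$timepoint), , drop = FALSE] +
    matrix(stats::rnorm(nrow(design) * n_factors, sd = factor_noise_sd),
           nrow(design), n_factors)
  z <- scale(z)
  dimnames(z) <- list(design$sample_id, paste0("F", seq_len(n_factors)))
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z
}

#' Simulate a spectral-count proteome table with known ground truth
#'
#' Latent relative abundances per protein and sample are a log-normal
#' baseline times a multiplicative responder time profile times replicate
#' noise, normalized to sum to one per sample. Expected PSM counts follow
#' the length-weighted law `depth * L_k * a_ks / sum_j L_j a_js`, under
#' which NSAF is an unbiased plug-in estimate of relative abundance.
#' Observed counts are Poisson draws around the expectation (or the exact
#' expectation when `count_law = "expected"`); expected counts below
#' `dropout_threshold` are deterministically recorded as 0 (not detected).
#'
#' When `truth_cfg` carries latent-factor scores, `block_proteins` proteins
#' per factor have their abundance driven by the factor so that within-block
#' pairwise correlations equal `factor_loading`. Members are drawn from just
#' below the top decile of expected counts: abundant enough that counting
#' noise is negligible, yet not among the dominant proteins that control the
#' NSAF denominator.
#'
#' @param design Sample table from [generate_design()].
#' @param params A [sim_params()] object.
#' @param truth_cfg Optional list with elements `factor_scores` (matrix from
#'   [simulate_factor_scores()]) used to plant correlated blocks.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A list with `counts` (a `spectral_counts` object: integer-ish
#'   matrix proteins x samples plus a `length` vector and the design) and
#'   `truth` (responder table and profiles, block memberships, the planted
#'   relative abundances, and the dropout mask).
#' @export
simulate_proteome <- function(design, params = sim_params(), truth_cfg = NULL,
                              seed = params$seed) {
  validate_sim_params(params)
  set.seed(seed)
  n <- params$n_proteins
  ns <- nrow(design)
  ids <- sprintf("P%04d", seq_len(n))
  lens <- sample(seq(params$length_range[1], params$length_range[2]), n,
                 replace = TRUE)
  baseline <- stats::rlnorm(n, meanlog = 0, sdlog = params$baseline_sdlog)
  names(baseline) <- names(lens) <- ids

  tp <- sort(unique(design$timepoint))
  tp_idx <- match(design$timepoint, tp)

  ## latent-factor block members, assigned round robin over factors
  block <- integer(0)
  z <- NULL
  ## factor_loading parameterizes the within-block pairwise correlation;
  ## the feature-to-factor correlation is its square root
  lam <- sqrt(params$factor_loading)
  if (!is.null(truth_cfg$factor_scores) && params$block_proteins > 0L) {
    z <- truth_cfg$factor_scores[design$sample_id, , drop = FALSE]
    n_block <- min(ncol(z) * params$block_proteins, n)
    ## Block members come from just below the top decile of expected counts
    ## (baseline x length, the quantity that governs dropout and counting
    ## noise): abundant enough that Poisson noise is negligible, but not the
    ## dominant proteins that control the NSAF denominator -- those stay
    ## stable, keeping the compositional distortion of NSAF second-order.
    ranked <- order(baseline * lens, decreasing = TRUE)
    skip <- ceiling(0.1 * n)
    members <- ranked[seq(skip + 1L, length.out = n_block)]
    block <- structure(rep(seq_len(ncol(z)), length.out = n_block),
                       names = ids[members])
  }

  ## planted responders (multiplicative profiles), drawn outside the blocks.
  ## Responders are planted above the bottom baseline quartile: a planted
  ## effect on a protein too scarce to be quantified is unrecoverable by
  ## construction, and the emulated study likewise defines its differential
  ## set within the confidently quantified (abundance-filtered) proteins.
  free <- setdiff(seq_len(n), match(names(block), ids))
  free <- free[baseline[free] >= stats::quantile(baseline, 0.25)]
  n_resp <- min(round(params$responder_frac * n), length(free))
  resp_idx <- sort(sample(free, n_resp))
  profiles <- matrix(1, n_resp, length(tp),
                     dimnames = list(ids[resp_idx], as.character(tp)))
  direction <- character(n_resp)
  peak <- integer(n_resp)
  if (n_resp > 0L) {
    ## peak times follow the starvation-factor intensity: most differential
    ## proteins in the emulated experiment respond to the nutrient status,
    ## which is what groups deep-starvation samples apart from control and
    ## recovered samples
    peak_w <- exp(factor_profiles(tp, 1L)[, 1])
    peak <- sample(seq_along(tp), n_resp, replace = TRUE, prob = peak_w)
    direction <- sample(c("up", "down"), n_resp, replace = TRUE)
    nt <- length(tp)
    ## Responses lag the nutrient switch: a protein responding to the
    ## starved state is still near control level shortly after depletion
    ## starts and still starvation-like shortly after replenishment.
    ## Starvation-phase responders therefore track the starvation-state
    ## profile (modulated around their own peak time); replete-phase
    ## responders are narrow transients. Each profile attains the full
    ## effect_size contrast at its peak.
    p1 <- factor_profiles(tp, 1L)[, 1]
    p1n <- pmax(p1, 0) / max(p1)
    for (i in seq_len(n_resp)) {
      j <- peak[i]
      d <- abs(seq_len(nt) - j)
      if (p1[j] > 1) {
        w <- 0.6 * p1n + 0.4 * pmax(0, 1 - d / 2)
        w <- w / max(w)
      } else {
        w <- pmax(0, 1 - d / 1.5)
      }
      profiles[i, ] <- params$effect_size^(if (direction[i] == "up") w else -w)
    }
  }

  log_a <- matrix(log(baseline), n, ns, dimnames = list(ids, design$sample_id))
  if (n_resp > 0L) {
    log_a[resp_idx, ] <- log_a[resp_idx, ] + log(profiles)[, tp_idx, drop = FALSE]
  }
  noise <- matrix(stats::rnorm(n * ns, sd = params$noise_sd), n, ns)
  if (length(block)) {
    bi <- match(names(block), ids)
    eps <- matrix(stats::rnorm(length(bi) * ns), length(bi), ns)
    noise[bi, ] <- lam * t(z)[block, , drop = FALSE] + sqrt(1 - lam^2) * eps
  }
  log_a <- log_a + noise
  a <- exp(log_a)
  a <- sweep(a, 2, colSums(a), "/")

  wls <- a * lens
  expected <- params$depth * sweep(wls, 2, colSums(wls), "/")
  observed <- if (params$count_law == "poisson") {
    matrix(stats::rpois(n * ns, lambda = expected), n, ns,
           dimnames = dimnames(expected))
  } else {
    expected
  }
  dropout <- expected < params$dropout_threshold
  observed[dropout] <- 0

  counts <- structure(
    list(counts = observed, length = lens, design = design),
    class = "spectral_counts"
  )
  truth <- list(
    responders = data.frame(
      feature_id = ids[resp_idx],
      direction = direction,
      peak_time = if (n_resp > 0L) tp[peak] else numeric(0),
      stringsAsFactors = FALSE
    ),
    profiles = profiles,
    block_memberships = block,
    rel_abundance = a,
    expected_counts = expected,
    dropout_mask = dropout
  )
  list(counts = counts, truth = truth)
}

#' @export
print.spectral_counts <- function(x, ...) {
  cat("<spectral_counts> ", nrow(x$counts), " proteins x ", ncol(x$counts),
      " samples; total PSM per sample ~ ",
      round(mean(colSums(x$counts))), "\n", sep = "")
  invisible(x)
}

#' Simulate metabolite peak areas and physiological measurements
#'
#' Block metabolites follow their latent factor on the log scale at
#' correlation `factor_loading` (private noise variance `1 - loading^2`);
#' the remaining metabolites are independent log-normal noise around their
#' baselines. Peak areas are strictly positive. Physiology variables are
#' noisy affine images of designated factors (variable `j` maps to factor
#' `1 + (j-1) mod n_factors`); the first variable is generated on an
#' Fv/Fm-like scale (baseline 0.7, negative loading), the others on
#' arbitrary positive scales.
#'
#' @inheritParams simulate_proteome
#' @return List with `metabolites` (matrix features x samples),
#'   `physio` (matrix variables x samples, 0 rows if `n_physio = 0`) and
#'   `truth` (block memberships for both tables and the factor scores used).
#' @export
simulate_metabolome_physio <- function(design, params = sim_params(),
                                       truth_cfg = NULL, seed = params$seed) {
  validate_sim_params(params)
  set.seed(seed)
  ns <- nrow(design)
  nm <- params$n_metabolites
  ids <- sprintf("M%03d", seq_len(nm))

  z <- truth_cfg$factor_scores
  if (is.null(z)) {
    z <- simulate_factor_scores(design, params$n_factors,
                                params$factor_noise_sd, seed = seed + 1L)
  }
  z <- z[design$sample_id, , drop = FALSE]
  nf <- ncol(z)
  ## within-block pairwise correlation = factor_loading (see simulate_proteome)
  lam <- sqrt(params$factor_loading)

  baseline <- stats::rlnorm(nm, meanlog = log(1e6), sdlog = params$baseline_sdlog)
  n_block <- min(nf * params$block_metabolites, nm)
  ## as for proteins: block members sit below the top abundance decile so the
  ## per-sample total (the normalization denominator) is dominated by stable
  ## metabolites and sample-centric normalization stays well behaved
  ranked <- order(baseline, decreasing = TRUE)
  skip <- min(ceiling(0.1 * nm), nm - n_block)
  bi <- ranked[seq(skip + 1L, length.out = n_block)]
  block <- structure(rep(seq_len(nf), length.out = n_block), names = ids[bi])
  log_area <- matrix(log(baseline), nm, ns, dimnames = list(ids, design$sample_id))
  noise <- matrix(stats::rnorm(nm * ns, sd = params$noise_sd), nm, ns)
  if (n_block > 0L) {
    eps <- matrix(stats::rnorm(n_block * ns), n_block, ns)
    noise[bi, ] <- lam * t(z)[block, , drop = FALSE] + sqrt(1 - lam^2) * eps
  }
  metabolites <- exp(log_area + noise)

  np <- params$n_physio
  phys_block <- integer(0)
  physio <- matrix(numeric(0), 0, ns,
                   dimnames = list(character(0), design$sample_id))
  if (np > 0L) {
    phys_names <- c("FvFm", "fresh_weight", "total_lipid", "fatty_acid",
                    "chlorophyll")
    if (np > length(phys_names)) {
      phys_names <- c(phys_names, sprintf("physio_%02d", seq_len(np - length(phys_names))))
    }
    phys_names <- phys_names[seq_len(np)]
    phys_block <- structure(1L + (seq_len(np) - 1L) %% nf, names = phys_names)
    intercept <- c(0.7, 10, 5, 2, 8)[pmin(seq_len(np), 5L)]
    slope <- c(-0.05, 2, 1.5, 0.5, 2)[pmin(seq_len(np), 5L)]
    physio <- matrix(0, np, ns, dimnames = list(phys_names, design$sample_id))
    for (j in seq_len(np)) {
      physio[j, ] <- intercept[j] + slope[j] * z[, phys_block[j]] +
        stats::rnorm(ns, sd = abs(slope[j]) * params$physio_noise_sd)
    }
  }

  list(
    metabolites = metabolites,
    physio = physio,
    truth = list(
      block_memberships = c(block, phys_block),
      factor_scores = z
    )
  )
}

#' Simulate standalone lag-1 causal series
#'
#' Drivers are standard Gaussian white noise; each planted target satisfies
#' `y_t = beta * x_{t-1} + e_t` with innovation SD `causal_noise_sd`
#' (the first target value uses an unobserved pre-series driver value so
#' every reported point follows the same law). Additional null series are
#' independent white noise.
#'
#' @inheritParams simulate_proteome
#' @return List with `series` (matrix series x time, rows named
#'   `X<i>`/`Y<i>` for planted pairs and `N<i>` for null series) and
#'   `truth` (`causal_pairs` data frame with the planted coefficients).
#' @export
simulate_causal_series <- function(params = sim_params(), truth_cfg = NULL,
                                   seed = params$seed) {
  validate_sim_params(params)
  if (params$series_length < 10L) {
    stop("parameter error: `series_length` must be at least 10", call. = FALSE)
  }
  set.seed(seed)
  T <- params$series_length
  npair <- params$n_causal_pairs
  nnull <- params$n_null_series
  rows <- list()
  pairs <- data.frame(driver = character(0), target = character(0),
                      beta = numeric(0), stringsAsFactors = FALSE)
  for (i in seq_len(npair)) {
    x_full <- stats::rnorm(T + 1L)
    x <- x_full[-1L]
    y <- params$causal_beta * x_full[seq_len(T)] +
      stats::rnorm(T, sd = params$causal_noise_sd)
    rows[[sprintf("X%02d", i)]] <- x
    rows[[sprintf("Y%02d", i)]] <- y
    pairs <- rbind(pairs, data.frame(
      driver = sprintf("X%02d", i), target = sprintf("Y%02d", i),
      beta = params$causal_beta, stringsAsFactors = FALSE
    ))
  }
  for (i in seq_len(nnull)) {
    rows[[sprintf("N%02d", i)]] <- stats::rnorm(T)
  }
  series <- do.call(rbind, rows)
  colnames(series) <- sprintf("t%02d", seq_len(T))
  list(series = series, truth = list(causal_pairs = pairs))
}

#' Blank cells completely at random, never emptying a row or column
#'
#' Exactly `round(missing_rate * n_cells)` entries are set to `NA`,
#' sampled uniformly among cell orders that leave at least one observed
#' value in every feature and every sample (cells whose removal would empty
#' a row or column are skipped and resampled).
#'
#' @param table Numeric matrix (features x samples).
#' @param missing_rate Fraction of cells to blank, in [0, 1).
#' @param seed Integer seed.
#' @return List with `values` (the masked matrix) and `mask` (logical
#'   matrix, `TRUE` where blanked).
#' @export
inject_missingness <- function(table, missing_rate, seed = 1L) {
  stopifnot(is.matrix(table))
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("parameter error: `missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  n_cells <- length(table)
  n_target <- round(missing_rate * n_cells)
  mask <- matrix(FALSE, nrow(table), ncol(table), dimnames = dimnames(table))
  if (n_target == 0L) {
    return(list(values = table, mask = mask))
  }
  if (n_target > n_cells - max(nrow(table), ncol(table))) {
    stop("infeasible mask: rate would force an all-missing row or column",
         call. = FALSE)
  }
  set.seed(seed)
  row_left <- rep(ncol(table), nrow(table))
  col_left <- rep(nrow(table), ncol(table))
  order_cells <- sample.int(n_cells)
  taken <- 0L
  for (cell in order_cells) {
    if (taken == n_target) break
    i <- (cell - 1L) %% nrow(table) + 1L
    j <- (cell - 1L) %/% nrow(table) + 1L
    if (row_left[i] <= 1L || col_left[j] <= 1L) next
    mask[i, j] <- TRUE
    row_left[i] <- row_left[i] - 1L
    col_left[j] <- col_left[j] - 1L
    taken <- taken + 1L
  }
  if (taken < n_target) {
    stop("infeasible mask: could not place the requested number of blanks",
         call. = FALSE)
  }
  values <- table
  values[mask] <- NA_real_
  list(values = values, mask = mask)
}

#' Simulate a complete synthetic study
#'
#' Convenience orchestrator: expands the design, draws shared latent-factor
#' scores, simulates the proteome, metabolome and physiology tables around
#' them, injects MCAR missingness into the metabolome, and simulates the
#' standalone causal series. Per-stage seeds are derived deterministically
#' from `seed` so the whole study is reproducible from one integer.
#'
#' @param params A [sim_params()] object.
#' @param spec A [design_spec()] object.
#' @param seed Base integer seed (defaults to `spec$seed`).
#' @return List with `design`, `proteome` (`spectral_counts`),
#'   `metabolites`, `physio`, `series` and a merged `truth` record, which
#'   also carries `sample_groups` (the planted deep-starvation vs
#'   control-like partition of the timepoints, defined by thresholding the
#'   starvation factor profile) and the missingness mask.
#' @export
simulate_study <- function(params = sim_params(), spec = design_spec(),
                           seed = spec$seed) {
  design <- generate_design(spec)
  z <- simulate_factor_scores(design, params$n_factors,
                              params$factor_noise_sd, seed = seed)
  prot <- simulate_proteome(design, params, truth_cfg = list(factor_scores = z),
                            seed = seed + 1L)
  mp <- simulate_metabolome_physio(design, params,
                                   truth_cfg = list(factor_scores = z),
                                   seed = seed + 2L)
  met <- mp$metabolites
  miss <- inject_missingness(met, params$missing_rate, seed = seed + 3L)
  series <- simulate_causal_series(params, seed = seed + 4L)

  prof <- factor_profiles(spec$timepoints, params$n_factors)
  starved <- spec$timepoints[prof[, 1] > 1]

  truth <- list(
    responders = prot$truth$responders,
    profiles = prot$truth$profiles,
    block_memberships = c(
      stats::setNames(prot$truth$block_memberships,
                      paste0("protein:", names(prot$truth$block_memberships))),
      stats::setNames(mp$truth$block_memberships,
                      paste0(ifelse(grepl("^M", names(mp$truth$block_memberships)),
                                    "metabolite:", "physiology:"),
                             names(mp$truth$block_memberships)))
    ),
    rel_abundance = prot$truth$rel_abundance,
    dropout_mask = prot$truth$dropout_mask,
    factor_scores = z,
    missing_mask = miss$mask,
    causal_pairs = series$truth$causal_pairs,
    sample_groups = ifelse(design$timepoint %in% starved, "starved", "replete"),
    starved_timepoints = starved,
    seed = seed
  )
  list(
    design = design,
    proteome = prot$counts,
    metabolites = miss$values,
    physio = mp$physio,
    series = series$series,
    truth = truth
  )
}
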