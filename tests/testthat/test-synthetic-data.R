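test_that("design expansion matches the sampling layout", {
  d <- generate_design(design_spec())
  expect_equal(nrow(d), 24)
  expect_equal(unique(d$timepoint), c(0, 5, 24, 72, 77, 96))
  expect_equal(d$sample_id[1:4], c("T0_R1", "T0_R2", "T0_R3", "T0_R4"))

  expect_equal(nrow(generate_design(design_spec(0, 1))), 1)
  expect_error(design_spec(c(5, 0)), "strictly increasing")
  expect_error(design_spec(c(0, 5), 0), "positive integer")
})

test_that("simulation is deterministic given seed and parameters", {
  p <- sim_params(n_proteins = 40, n_metabolites = 12)
  a <- simulate_study(p, seed = 9)
  b <- simulate_study(p, seed = 9)
  expect_identical(a$proteome$counts, b$proteome$counts)
  expect_identical(a$metabolites, b$metabolites)
  expect_identical(a$physio, b$physio)
  expect_identical(a$series, b$series)
  expect_identical(a$truth$responders, b$truth$responders)
})

test_that("expected counts conserve the sampling depth per sample", {
  p <- sim_params(n_proteins = 80, n_metabolites = 10, dropout_threshold = 0)
  sim <- simulate_proteome(tiny_design(), p, seed = 3)
  expect_equal(colSums(sim$truth$expected_counts),
               rep(p$depth, 24), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("a single noise-free protein receives the whole depth", {
  p <- sim_params(n_proteins = 1, n_metabolites = 1, noise_sd = 0,
                  responder_frac = 0, block_proteins = 0,
                  dropout_threshold = 0, count_law = "expected")
  sim <- simulate_proteome(tiny_design(), p, seed = 1)
  expect_equal(unname(sim$counts$counts[1, ]), rep(p$depth, 24))
})

test_that("observed counts follow the Poisson law around the expectation", {
  ## z-scores of the draws against the closed-form expectation
  p <- sim_params(n_proteins = 200, dropout_threshold = 0)
  sim <- simulate_proteome(tiny_design(), p, seed = 11)
  e <- sim$truth$expected_counts
  z <- (sim$counts$counts - e) / sqrt(e)
  n_draws <- length(z)
  expect_lt(abs(mean(z)), 3 / sqrt(n_draws))   # mean within 3 SE of 0
  expect_lt(abs(stats::var(as.vector(z)) - 1), 0.1)
})

test_that("a planted multiplicative profile shows up monotonically in NSAF", {
  ## analytic expectation of NSAF under the generative law, no sampling noise
  design <- tiny_design()
  profile <- c(1, 2, 4, 8, 4, 1)
  lens <- c(300, 600, 900)
  base <- c(1, 1, 1)
  tp_idx <- match(design$timepoint, unique(design$timepoint))
  a <- rbind(base[1] * profile[tp_idx], base[2], base[3])
  a <- sweep(a, 2, colSums(a), "/")
  expected <- 1000 * sweep(a * lens, 2, colSums(a * lens), "/")
  dimnames(expected) <- list(c("r", "s1", "s2"), design$sample_id)
  nsaf <- compute_nsaf(expected, lengths = lens)
  prof_means <- tapply(nsaf["r", ], design$timepoint, mean)
  expect_true(all(diff(prof_means[1:4]) > 0))
})

test_that("latent blocks give collinear features at loading one and separated blocks at 0.9", {
  design <- tiny_design()
  p1 <- sim_params(n_metabolites = 12, factor_loading = 1, block_metabolites = 4)
  mp <- simulate_metabolome_physio(design, p1, seed = 2)
  bm <- mp$truth$block_memberships
  members <- names(bm)[grepl("^M", names(bm)) & bm == 1]
  cc <- stats::cor(t(log(mp$metabolites[members, ])))
  expect_equal(abs(cc), matrix(1, length(members), length(members)),
               tolerance = 1e-12, ignore_attr = TRUE)

  p2 <- sim_params(n_metabolites = 20, factor_loading = 0.9, block_metabolites = 5)
  mp2 <- simulate_metabolome_physio(design, p2, seed = 5)
  bm2 <- mp2$truth$block_memberships
  met <- names(bm2)[grepl("^M", names(bm2))]
  cc2 <- stats::cor(t(log(mp2$metabolites[met, ])))
  same <- outer(bm2[met], bm2[met], "==")
  diag(same) <- NA
  expect_gt(min(abs(cc2[which(same)])), max(abs(cc2[which(!same)])))
})

test_that("degenerate sizes and invalid loadings are handled", {
  design <- tiny_design()
  mp <- simulate_metabolome_physio(design, sim_params(n_physio = 0), seed = 1)
  expect_equal(nrow(mp$physio), 0)
  expect_error(sim_params(factor_loading = 1.5), "factor_loading")
  expect_error(sim_params(factor_loading = 0), "factor_loading")
})

test_that("causal series carry the planted lag-1 signal", {
  p <- sim_params(causal_beta = 0.9, causal_noise_sd = 0.1, series_length = 50)
  sim <- simulate_causal_series(p, seed = 4)
  for (i in seq_len(nrow(sim$truth$causal_pairs))) {
    x <- sim$series[sim$truth$causal_pairs$driver[i], ]
    y <- sim$series[sim$truth$causal_pairs$target[i], ]
    expect_gt(stats::cor(x[1:49], y[2:50]), 0.9)
  }
  expect_error(simulate_causal_series(sim_params(series_length = 9)),
               "at least 10")
})

test_that("null causal series are mutually independent white noise", {
  p <- sim_params(causal_beta = 0, causal_noise_sd = 1, series_length = 200,
                  n_causal_pairs = 3, n_null_series = 3)
  sim <- simulate_causal_series(p, seed = 8)
  cc <- stats::cor(t(sim$series))
  diag(cc) <- 0
  expect_lt(max(abs(cc)), 4 / sqrt(200))
})

test_that("missingness injection blanks the exact count without emptying rows or columns", {
  m <- named_matrix(1:100, 10, 10)
  out <- inject_missingness(m, 0.1, seed = 2)
  expect_equal(sum(is.na(out$values)), 10)
  expect_equal(sum(out$mask), 10)

  id <- inject_missingness(m, 0, seed = 2)
  expect_identical(id$values, m)
  expect_equal(sum(id$mask), 0)

  expect_error(inject_missingness(named_matrix(1:4, 2, 2), 0.99),
               "infeasible")

  for (s in 1:5) {
    out <- inject_missingness(named_matrix(rnorm(48), 6, 8), 0.3, seed = s)
    expect_true(all(rowSums(!is.na(out$values)) >= 1))
    expect_true(all(colSums(!is.na(out$values)) >= 1))
  }
})
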