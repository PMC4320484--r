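test_that("NSAF matches the hand-evaluated formula", {
  m <- named_matrix(c(10, 10), 2, 1)
  expect_equal(unname(compute_nsaf(m, lengths = c(100, 200))[, 1]),
               c(2 / 3, 1 / 3))
  one <- named_matrix(7, 1, 2)
  expect_equal(unname(compute_nsaf(one, lengths = 500)), matrix(1, 1, 2))
  bad <- named_matrix(c(1, 2, 0, 0), 2, 2)
  expect_error(compute_nsaf(bad, lengths = c(100, 100)), "s02")
})

test_that("NSAF columns sum to one and zeros stay zero for random inputs", {
  set.seed(71)
  for (i in 1:10) {
    m <- named_matrix(rpois(60, 5), 12, 5)
    lens <- sample(100:1500, 12)
    if (any(colSums(m) == 0)) next
    nsaf <- compute_nsaf(m, lengths = lens)
    expect_equal(colSums(nsaf), rep(1, 5), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(nsaf == 0, m == 0)
  }
})

test_that("NSAF is invariant to uniform per-sample PSM scaling", {
  set.seed(72)
  m <- named_matrix(rpois(40, 20) + 1, 8, 5)
  lens <- sample(100:1500, 8)
  doubled <- m
  doubled[, 3] <- 2L * m[, 3]
  expect_equal(compute_nsaf(m, lengths = lens),
               compute_nsaf(doubled, lengths = lens))
})

test_that("NSAF recovers planted relative abundances exactly without noise", {
  p <- sim_params(n_proteins = 50, noise_sd = 0, block_proteins = 0,
                  dropout_threshold = 0, count_law = "expected")
  sim <- simulate_proteome(tiny_design(), p, seed = 6)
  nsaf <- compute_nsaf(sim$counts)
  expect_equal(nsaf, sim$truth$rel_abundance, tolerance = 1e-9)
})

test_that("minimum-abundance filter applies the threshold to the per-protein maximum", {
  m <- rbind(low = c(0.0009, 0.0005), keep = c(0.0011, 0.0001),
             rest = c(0.998, 0.9984))
  colnames(m) <- c("s1", "s2")
  out <- filter_min_abundance(m, tau = 0.001)
  expect_identical(rownames(out), c("keep", "rest"))

  all_kept <- filter_min_abundance(m, tau = .Machine$double.xmin)
  expect_identical(rownames(all_kept), rownames(m))

  ## brute-force scan over a grid straddling tau
  set.seed(73)
  g <- named_matrix(10^runif(600, -5, -1), 100, 6)
  out <- filter_min_abundance(g, tau = 0.001)
  expect_equal(nrow(out), sum(apply(g, 1, max) >= 0.001))

  expect_identical(filter_min_abundance(out, tau = 0.001), out,
                   ignore_attr = TRUE)  # idempotent
})

test_that("replicate-presence filter implements both clauses", {
  design <- tiny_design()
  m <- matrix(0, 3, 24, dimnames = list(c("full72", "spread5", "three"),
                                        design$sample_id))
  m["full72", design$timepoint == 72] <- 1                      # all 4 reps, one time
  m["spread5", c("T0_R1", "T5_R2", "T24_R3", "T72_R4", "T77_R1")] <- 1  # 5 distinct times
  m["three", c("T24_R1", "T24_R2", "T24_R3")] <- 1              # fails both
  out <- filter_replicate_presence(m, design)
  expect_identical(rownames(out), c("full72", "spread5"))
  expect_identical(filter_replicate_presence(out, design), out,
                   ignore_attr = TRUE)
  expect_error(filter_replicate_presence(m[, 1:10], design), "mismatch")
})

test_that("metabolite presence filter uses the strict fallback inequality", {
  design <- tiny_design()
  m <- matrix(0, 3, 24, dimnames = list(c("in19", "in18", "everywhere"),
                                        design$sample_id))
  set.seed(74)
  ## 3 detections per timepoint = 18 total, never a full replicate set
  three_per_tp <- unlist(lapply(split(seq_len(24), design$timepoint),
                                function(ix) sample(ix, 3)))
  m["in18", three_per_tp] <- 1
  m["in19", sample(seq_len(24), 19)] <- 1   # 19 anywhere -> retained
  m["everywhere", ] <- 1
  out <- filter_metabolite_presence(m, design, min_samples = 18)
  expect_true(all(c("in19", "everywhere") %in% rownames(out)))
  expect_false("in18" %in% rownames(out))

  ## strictness of the > clause isolated at a lower threshold
  m2 <- matrix(0, 2, 24, dimnames = list(c("eleven", "ten"), design$sample_id))
  m2["eleven", three_per_tp[1:11]] <- 1
  m2["ten", three_per_tp[1:10]] <- 1
  out2 <- filter_metabolite_presence(m2, design, min_samples = 10)
  expect_identical(rownames(out2), "eleven")
})

test_that("sample-centric normalization divides by per-sample totals", {
  m <- named_matrix(c(2, 3, 5), 3, 1)
  expect_equal(unname(normalize_metabolites(m)[, 1]), c(0.2, 0.3, 0.5))
  expect_equal(unname(normalize_metabolites(named_matrix(42, 1, 1))[1, 1]), 1)
  expect_error(normalize_metabolites(named_matrix(c(-1, 2), 2, 1)),
               "non-negative")
  expect_error(normalize_metabolites(named_matrix(c(0, 0), 2, 1)),
               "degenerate")
})

test_that("T0 normalization divides flagged variables by the control mean", {
  design <- tiny_design()
  phys <- matrix(0.6, 2, 24, dimnames = list(c("FvFm", "fresh_weight"),
                                             design$sample_id))
  phys["fresh_weight", ] <- 5
  phys["fresh_weight", design$timepoint == 0] <- 2
  phys["fresh_weight", "T96_R1"] <- 3
  out <- normalize_physio_t0(phys, design)
  expect_equal(out["fresh_weight", "T96_R1"], 1.5)      # 3 / mean(2,2,2,2)
  expect_equal(out["FvFm", ], phys["FvFm", ])           # exempt passthrough
  expect_equal(unname(out["fresh_weight", design$timepoint == 0]), rep(1, 4))

  allsame <- matrix(4, 1, 24, dimnames = list("lipid", design$sample_id))
  expect_equal(unname(normalize_physio_t0(allsame, design)[1, ]), rep(1, 24))

  zero <- matrix(c(rep(0, 4), rep(2, 20)), 1, 24,
                 dimnames = list("lipid", design$sample_id))
  expect_error(normalize_physio_t0(zero, design), "degenerate baseline")
})

test_that("block merging stacks features with unique prefixed IDs", {
  design <- tiny_design()
  mk <- function(n, prefix) named_matrix(seq_len(n * 24), n, 24) |>
    (\(m) { dimnames(m) <- list(sprintf("%s%d", prefix, seq_len(n)),
                                design$sample_id); m })()
  fm <- merge_blocks(mk(10, "p"), mk(5, "m"), mk(2, "v"), design)
  expect_equal(nrow(fm$values), 17)
  expect_equal(as.vector(table(fm$blocks)), c(10, 5, 2))

  ## duplicate IDs across blocks stay distinct after prefixing
  fm2 <- merge_blocks(mk(2, "x"), mk(2, "x"), mk(1, "x"), design)
  expect_equal(anyDuplicated(rownames(fm2$values)), 0)

  other <- mk(2, "m")
  colnames(other) <- paste0("z", seq_len(24))
  expect_error(merge_blocks(mk(2, "p"), other, mk(1, "v"), design), "mismatch")
})
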