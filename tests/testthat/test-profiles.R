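test_that("percent-of-max profiles follow the definition", {
  design <- tiny_design()
  vals <- c(2, 4, 8, 4, 2, 1)
  m <- matrix(rep(vals, each = 4), 1, 24, dimnames = list("f", design$sample_id))
  out <- percent_of_max(m, design)
  expect_equal(unname(out[1, ]), c(25, 50, 100, 50, 25, 12.5))

  konst <- matrix(3, 1, 24, dimnames = list("k", design$sample_id))
  expect_equal(unname(percent_of_max(konst, design)[1, ]), rep(100, 6))

  ## replicate averaging before normalization, hand computation
  m2 <- matrix(0, 1, 24, dimnames = list("g", design$sample_id))
  m2[1, ] <- rep(c(1, 3, 0, 0, 0, 0), each = 4) + rep(c(0, 2), 12)
  means <- tapply(m2[1, ], design$timepoint, mean)
  expect_equal(unname(percent_of_max(m2, design)[1, ]),
               as.numeric(100 * means / max(means)))

  zero <- matrix(0, 1, 24, dimnames = list("z", design$sample_id))
  pz <- percent_of_max(rbind(m, zero), design)
  expect_equal(attr(pz, "excluded"), "z")
  expect_false("z" %in% rownames(pz))
})

test_that("percent-of-max is idempotent and invariant to positive rescaling", {
  design <- tiny_design()
  set.seed(131)
  m <- matrix(rexp(72), 3, 24,
              dimnames = list(paste0("f", 1:3), design$sample_id))
  p1 <- percent_of_max(m, design)
  expect_equal(percent_of_max(10 * m, design), p1)
  tp_design <- data.frame(sample_id = colnames(p1),
                          timepoint = as.numeric(colnames(p1)),
                          replicate = 1)
  expect_equal(percent_of_max(p1, tp_design), p1)
})

test_that("bin aggregation averages members and reports the unmapped", {
  prof <- rbind(a = c(100, 0, 0), b = c(0, 100, 0))
  colnames(prof) <- c(0, 5, 24)
  bm <- data.frame(feature_id = c("a", "b"), bin = "one")
  agg <- bin_aggregate(prof, bm)
  expect_equal(agg$profile$mean, c(50, 50, 0))
  expect_equal(agg$profile$n_members, rep(2L, 3))

  empty <- bin_aggregate(prof, bm, significant = character(0))
  expect_equal(nrow(empty$profile), 0)

  set.seed(132)
  prof3 <- matrix(runif(60, 0, 100), 10, 6,
                  dimnames = list(paste0("f", 1:10), c(0, 5, 24, 72, 77, 96)))
  bm3 <- data.frame(feature_id = paste0("f", 1:10),
                    bin = rep(c("x", "y", "z"), length.out = 10))
  agg3 <- bin_aggregate(prof3, bm3)
  for (b in c("x", "y", "z")) {
    members <- bm3$feature_id[bm3$bin == b]
    expect_equal(agg3$profile$mean[agg3$profile$bin == b],
                 unname(colMeans(prof3[members, , drop = FALSE])))
    expect_equal(agg3$profile$sd[agg3$profile$bin == b],
                 unname(apply(prof3[members, , drop = FALSE], 2, sd)))
  }
  sing <- bin_aggregate(prof3, data.frame(feature_id = "f1", bin = "solo"))
  expect_true(all(sing$profile$small_bin))
  expect_true(all(paste0("f", 2:10) %in% sing$unmapped))
})

test_that("biclustering merges identical columns first and matches an agglomeration oracle", {
  m <- matrix(c(1, 2, 3, 1, 2, 3, 9, 9, 9, 0, 1, 5), 3, 4,
              dimnames = list(paste0("r", 1:3), paste0("c", 1:4)))
  bc <- bicluster_heatmap(m)
  expect_equal(min(bc$heights$cols), 0)         # identical c1/c2 merge at 0
  first_merge <- bc$col_hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))

  ## naive complete-linkage oracle on a 5x4 fixture: check the merge heights
  set.seed(133)
  f <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("r", 1:5), paste0("c", 1:4)))
  bc2 <- bicluster_heatmap(f)
  d <- as.matrix(dist(f))
  clusters <- as.list(seq_len(5))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(bc2$row_hclust$height, heights, tolerance = 1e-12)

  expect_error(bicluster_heatmap(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(bicluster_heatmap(matrix(1, 1, 3)), "at least 2")
})

test_that("planted sample groups are recovered exactly on a two-group matrix", {
  set.seed(134)
  grp <- rep(c("ctrl", "starved"), each = 4)
  m <- matrix(rnorm(80), 10, 8,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  m[1:6, grp == "starved"] <- m[1:6, grp == "starved"] + 5
  bc <- bicluster_heatmap(m)
  cut <- stats::cutree(bc$col_hclust, k = 2)
  expect_equal(ari_oracle(cut, grp), 1)
})

test_that("dendrograms serialize to parseable Newick", {
  set.seed(135)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("r", 1:6), paste0("c", 1:4)))
  bc <- bicluster_heatmap(m)
  nwk <- as_newick(bc$row_hclust)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, paste0("r", 1:6))
})
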