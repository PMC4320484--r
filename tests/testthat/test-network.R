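test_that("sPLS similarity reduces to a single product for one component", {
  set.seed(111)
  x <- autoscale(matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("x", 1:5))))
  y <- autoscale(matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("y1", "y2"))))
  model <- spls(x, y, ncomp = 1, keepX = 5)
  sim <- spls_similarity(model, x, y)
  ref <- tcrossprod(stats::cor(x, model$scores), stats::cor(y, model$scores))
  expect_equal(unclass(sim), unclass(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("full-rank non-sparse similarity reproduces direct correlations", {
  set.seed(112)
  x <- autoscale(matrix(rnorm(80), 20, 4, dimnames = list(NULL, paste0("x", 1:4))))
  y <- autoscale(matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("y1", "y2"))))
  model <- spls(x, y, ncomp = 4, keepX = 4)
  sim <- spls_similarity(model, x, y)
  direct <- stats::cor(x, y)
  expect_equal(unclass(sim), unclass(direct), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("responses orthogonal to all scores get zero similarity", {
  set.seed(113)
  x <- autoscale(matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("x", 1:5))))
  y <- autoscale(matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("y1", "y2"))))
  model <- spls(x, y, ncomp = 2, keepX = 5)
  y_orth <- stats::resid(stats::lm(rnorm(12) ~ model$scores))
  y_orth <- matrix(y_orth / stats::sd(y_orth), 12, 1,
                   dimnames = list(NULL, "yo"))
  sim <- spls_similarity(model, x, y_orth)
  expect_lt(max(abs(sim)), 1e-10)
})

test_that("pairwise correlations match a from-scratch covariance oracle", {
  set.seed(114)
  m <- named_matrix(rnorm(200), 20, 10)
  cc <- pairwise_correlation(m)
  expect_equal(diag(cc), rep(1, 20), ignore_attr = TRUE)
  for (pair in list(c(1, 2), c(3, 17), c(20, 5))) {
    a <- m[pair[1], ]; b <- m[pair[2], ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(cc[pair[1], pair[2]], oracle, tolerance = 1e-12)
  }
  m2 <- rbind(m, anti = -m[1, ])
  cc2 <- pairwise_correlation(m2)
  expect_equal(cc2["f01", "anti"], -1, tolerance = 1e-12)
  m3 <- rbind(m, konst = 1)
  expect_warning(cc3 <- pairwise_correlation(m3), "konst")
  expect_true(all(is.na(cc3["konst", setdiff(rownames(m3), "konst")])))
})

test_that("thresholding matches a brute-force scan and behaves monotonically", {
  set.seed(115)
  m <- named_matrix(rnorm(80), 8, 10)
  m[2, ] <- m[1, ] + rnorm(10, sd = 0.1)   # strong planted pair
  cc <- pairwise_correlation(m)
  net <- threshold_network(cc, 0.9)
  scan <- which(abs(cc) >= 0.9 & upper.tri(cc), arr.ind = TRUE)
  expect_equal(nrow(net$edges), nrow(scan))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(net$edges$source, net$edges$target),
                  key(rownames(cc)[scan[, 1]], colnames(cc)[scan[, 2]]))
  expect_true(all(abs(net$edges$weight) >= 0.9))
  expect_false(any(net$edges$source == net$edges$target))

  counts <- vapply(c(0.5, 0.7, 0.9), function(ct)
    nrow(threshold_network(cc, ct)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))

  empty <- threshold_network(matrix(c(1, 0.99, 0.99, 1), 2, 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))),
                             cutoff = 1)
  expect_equal(nrow(empty$edges), 0)
  expect_error(threshold_network(cc, 0), "cutoff")
})

test_that("networks are deterministic and export to SIF and GraphML", {
  set.seed(116)
  m <- named_matrix(rnorm(60), 6, 10)
  m[2, ] <- m[1, ] + rnorm(10, sd = 0.05)
  m[4, ] <- -m[3, ] + rnorm(10, sd = 0.05)
  cc <- pairwise_correlation(m)
  blocks <- stats::setNames(rep(c("protein", "metabolite"), 3), rownames(m))
  n1 <- threshold_network(cc, 0.8, blocks)
  n2 <- threshold_network(cc, 0.8, blocks)
  expect_identical(n1, n2)
  expect_true(all(c("+", "-") %in% n1$edges$sign))

  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  write_sif(n1, sif)
  write_graphml(n1, gml)
  back <- utils::read.delim(sif)
  expect_equal(nrow(back), nrow(n1$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(n1$nodes))
  expect_equal(igraph::gsize(g), nrow(n1$edges))

  merged <- merge_networks(n1, threshold_network(cc, 0.9, blocks,
                                                 provenance = "spls-similarity"))
  expect_true(all(c("pairwise-correlation") %in% merged$edges$provenance))
})
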