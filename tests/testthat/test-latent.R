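test_that("autoscaling centers, scales and round-trips", {
  x <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f1"))
  expect_equal(unname(autoscale(x)[, 1]), c(-1, 0, 1))
  set.seed(101)
  m <- matrix(rnorm(40, sd = 3), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_equal(unscale(autoscale(m)), m, tolerance = 1e-12)
  m2 <- cbind(m, konst = 1)
  expect_warning(out <- autoscale(m2), "konst")
  expect_false("konst" %in% colnames(out))
})

test_that("PCA matches an eigendecomposition oracle up to sign", {
  set.seed(102)
  x <- autoscale(matrix(rnorm(12), 4, 3, dimnames = list(NULL, paste0("f", 1:3))))
  model <- pca(x, ncomp = 3)
  ev <- eigen(crossprod(x))
  for (h in 1:3) {
    score_oracle <- drop(x %*% ev$vectors[, h])
    expect_equal(abs(model$scores[, h]), abs(score_oracle),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(model$explained_variance, ev$values / sum(ev$values),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA structure: perfect correlation, variance ordering, orthogonality, sign convention", {
  two <- autoscale(matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2,
                          dimnames = list(NULL, c("a", "b"))))
  m <- pca(two, ncomp = 2)
  expect_equal(m$explained_variance[1], 1, tolerance = 1e-12)

  set.seed(103)
  x <- autoscale(matrix(rnorm(80), 10, 8, dimnames = list(NULL, paste0("f", 1:8))))
  model <- pca(x, ncomp = 5)
  expect_true(all(diff(model$explained_variance) <= 1e-12))
  expect_lte(sum(model$explained_variance), 1 + 1e-12)
  gram <- crossprod(model$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  for (h in 1:5) {
    expect_gt(model$loadings[which.max(abs(model$loadings[, h])), h], 0)
  }
  expect_error(pca(x, ncomp = 10), "ncomp")
})

test_that("non-sparse one-component sPLS equals the leading singular vector of X'Y", {
  set.seed(104)
  x <- autoscale(matrix(rnorm(60), 12, 5, dimnames = list(NULL, paste0("x", 1:5))))
  y <- autoscale(matrix(rnorm(12), 12, 1, dimnames = list(NULL, "y")))
  model <- spls(x, y, ncomp = 1, keepX = 5)
  m <- drop(crossprod(x, y))
  u_ref <- m / sqrt(sum(m^2))
  expect_equal(abs(drop(model$weights)), abs(u_ref), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("full-keepX sPLS scores equal a from-scratch NIPALS PLS2 oracle", {
  set.seed(105)
  x <- autoscale(matrix(rnorm(120), 15, 8, dimnames = list(NULL, paste0("x", 1:8))))
  y <- autoscale(matrix(rnorm(45), 15, 3, dimnames = list(NULL, paste0("y", 1:3))))
  model <- spls(x, y, ncomp = 3, keepX = 8)
  oracle <- nipals_pls2_oracle(x, y, 3)
  for (h in 1:3) {
    expect_equal(abs(model$scores[, h]), abs(oracle[, h]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  gram <- crossprod(model$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)   # deflation orthogonality
  expect_equal(sqrt(colSums(model$weights^2)), rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sPLS agrees with the reference mixOmics implementation when not sparse", {
  set.seed(106)
  x <- autoscale(matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("x", 1:10))))
  y <- autoscale(matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("y", 1:3))))
  model <- spls(x, y, ncomp = 2, keepX = 10)
  ref <- mixOmics::spls(x, y, ncomp = 2, keepX = c(10, 10), mode = "regression",
                        scale = FALSE)
  for (h in 1:2) {
    expect_equal(abs(model$scores[, h]), abs(ref$variates$X[, h]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("keepX controls the support size exactly", {
  set.seed(107)
  x <- autoscale(matrix(rnorm(100), 10, 10, dimnames = list(NULL, paste0("x", 1:10))))
  y <- autoscale(matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("y1", "y2"))))
  model <- spls(x, y, ncomp = 3, keepX = 1)
  expect_equal(colSums(model$weights != 0), rep(1, 3), ignore_attr = TRUE)
  m2 <- spls(x, y, ncomp = 2, keepX = c(4, 7))
  expect_equal(unname(colSums(m2$weights != 0)), c(4, 7))
})

test_that("PLS-DA separates separable classes and collapses under permutation", {
  set.seed(108)
  n <- 20
  cl <- factor(rep(c("early", "late"), each = n / 2))
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  x[cl == "late", 1:3] <- x[cl == "late", 1:3] + 4
  xs <- autoscale(x)
  model <- plsda(xs, cl, ncomp = 2)
  s1 <- model$scores[, 1]
  expect_true(max(s1[cl == "early"]) < min(s1[cl == "late"]) ||
              min(s1[cl == "early"]) > max(s1[cl == "late"]))
  gap <- abs(mean(s1[cl == "early"]) - mean(s1[cl == "late"]))

  perm_gaps <- vapply(1:20, function(i) {
    clp <- sample(cl)
    sp <- plsda(xs, clp, ncomp = 1)$scores[, 1]
    abs(mean(sp[clp == "early"]) - mean(sp[clp == "late"]))
  }, numeric(1))
  expect_gt(gap, max(perm_gaps))

  expect_error(plsda(xs, factor(rep("one", n)), 1), "at least two classes")
  expect_warning(plsda(xs[1:3, ], factor(c("a", "a", "b")), 1), "single sample")
})
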