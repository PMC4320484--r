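## Small deterministic fixtures shared across tests.

tiny_design <- function(timepoints = c(0, 5, 24, 72, 77, 96), n_rep = 4) {
  generate_design(design_spec(timepoints, n_rep))
}

## feature x sample matrix with named dims
named_matrix <- function(values, nrow, ncol, prefix = "f") {
  matrix(values, nrow, ncol,
         dimnames = list(sprintf("%s%02d", prefix, seq_len(nrow)),
                         sprintf("s%02d", seq_len(ncol))))
}

## from-scratch Kruskal-Wallis with tie correction (independent oracle)
kw_oracle <- function(v, g) {
  g <- as.factor(g)
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  ties <- table(v)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}

## from-scratch one-way ANOVA + studentized-range p-values (independent oracle)
anova_oracle <- function(v, g) {
  g <- as.factor(g)
  k <- nlevels(g)
  n <- length(v)
  gm <- tapply(v, g, mean)
  ni <- tapply(v, g, length)
  ssb <- sum(ni * (gm - mean(v))^2)
  ssw <- sum((v - gm[g])^2)
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- utils::combn(levels(g), 2)
  ptuk <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    q <- abs(gm[pr[1]] - gm[pr[2]]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  names(ptuk) <- paste(pairs[1, ], pairs[2, ], sep = "-")
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE), tukey = ptuk)
}

## from-scratch BH step-up (independent oracle)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

## from-scratch Granger F via explicit normal equations (independent oracle)
granger_oracle <- function(x, y, lag = 1) {
  T <- length(y)
  resp <- y[(lag + 1):T]
  lagmat <- function(v) sapply(seq_len(lag), function(j) v[(lag + 1 - j):(T - j)])
  x0 <- cbind(1, lagmat(y))
  x1 <- cbind(x0, lagmat(x))
  beta0 <- solve(t(x0) %*% x0, t(x0) %*% resp)
  beta1 <- solve(t(x1) %*% x1, t(x1) %*% resp)
  rss0 <- sum((resp - x0 %*% beta0)^2)
  rss1 <- sum((resp - x1 %*% beta1)^2)
  df2 <- (T - lag) - (1 + 2 * lag)
  f <- ((rss0 - rss1) / lag) / (rss1 / df2)
  list(f = f, p = stats::pf(f, lag, df2, lower.tail = FALSE))
}

## from-scratch NIPALS PLS2 in regression mode (independent oracle)
nipals_pls2_oracle <- function(x, y, ncomp, tol = 1e-10, max_iter = 2000) {
  Tm <- matrix(0, nrow(x), ncomp)
  for (h in seq_len(ncomp)) {
    u <- svd(crossprod(x, y), nu = 1)$u[, 1]
    repeat {
      t_h <- x %*% u
      v <- crossprod(y, t_h); v <- v / sqrt(sum(v^2))
      s_h <- y %*% v
      u_new <- crossprod(x, s_h); u_new <- u_new / sqrt(sum(u_new^2))
      if (max(abs(u_new - u)) < tol) { u <- u_new; break }
      u <- u_new
    }
    t_h <- drop(x %*% u)
    c_h <- drop(crossprod(x, t_h)) / sum(t_h^2)
    d_h <- drop(crossprod(y, t_h)) / sum(t_h^2)
    x <- x - tcrossprod(t_h, c_h)
    y <- y - tcrossprod(t_h, d_h)
    Tm[, h] <- t_h
  }
  Tm
}

## adjusted Rand index between two labelings (small closed form)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
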