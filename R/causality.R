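#' Collapse a feature matrix to per-timepoint series
#'
#' In `"replicate_mean"` mode (default) replicates are averaged per
#' timepoint and each series is standardized to mean 0, SD 1, ordered by
#' time. Constant series cannot be standardized; they are kept but flagged
#' in the `degenerate` attribute and excluded from causality testing
#' downstream.
#'
#' @param matrix Feature x sample matrix or `feature_matrix`.
#' @param design Sample table from [generate_design()].
#' @param mode Series preparation mode; only `"replicate_mean"` is
#'   implemented (per-replicate pooling is a non-default research option).
#' @param standardize Standardize each series (default `TRUE`).
#' @return Matrix features x timepoints (columns ordered by time, named by
#'   the hour), with attribute `degenerate` naming constant series.
#' @export
prepare_series <- function(matrix, design, mode = "replicate_mean",
                           standardize = TRUE) {
  mode <- match.arg(mode, "replicate_mean")
  x <- fm_values(matrix)
  check_design_samples(design, colnames(x))
  x <- x[, design$sample_id, drop = FALSE]
  tp <- sort(unique(design$timepoint))
  if (length(tp) < 2L) {
    stop("design error: at least two timepoints are required", call. = FALSE)
  }
  means <- vapply(tp, function(t) {
    rowMeans(x[, design$timepoint == t, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) means <- matrix(means, nrow = 1)
  dimnames(means) <- list(rownames(x), as.character(tp))
  sds <- apply(means, 1, stats::sd)
  degenerate <- rownames(means)[sds == 0]
  out <- means
  if (standardize) {
    ok <- sds > 0
    out[ok, ] <- (means[ok, , drop = FALSE] - rowMeans(means[ok, , drop = FALSE])) /
      sds[ok]
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Lag-l Granger causality test for one ordered pair
#'
#' Nested-model F test: the restricted autoregression
#' `y_t ~ 1 + y_{t-1..t-l}` against the unrestricted model that adds
#' `x_{t-1..t-l}`. With `T` observations the statistic is
#' `F = [(RSS0 - RSS1)/l] / [RSS1 / (T - l - (1 + 2l))]` on
#' `(l, T - 3l - 1)` degrees of freedom. Degenerate inputs (constant `y`,
#' singular design such as `x` identical to `y`, or a perfect fit) yield a
#' flagged result with `p = 1` rather than an error.
#'
#' @param x Candidate driver series.
#' @param y Target series (same length, at least `2*lag + 3`).
#' @param lag Lag order (default 1).
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`,
#'   `degenerate`.
#' @export
granger_pair <- function(x, y, lag = 1) {
  if (length(x) != length(y)) {
    stop("series must have equal length", call. = FALSE)
  }
  T <- length(y)
  if (lag < 1) stop("`lag` must be >= 1", call. = FALSE)
  if (T < 2 * lag + 3) {
    stop("series too short: need T >= 2*lag + 3 = ", 2 * lag + 3,
         call. = FALSE)
  }
  df1 <- lag
  df2 <- (T - lag) - (1 + 2 * lag)
  degenerate <- list(statistic = 0, p_value = 1, df1 = df1, df2 = df2,
                     degenerate = TRUE)
  if (stats::sd(y) == 0) return(degenerate)
  resp <- y[(lag + 1):T]
  lagmat <- function(v) {
    vapply(seq_len(lag), function(j) v[(lag + 1 - j):(T - j)],
           numeric(T - lag))
  }
  x0 <- cbind(1, lagmat(y))
  x1 <- cbind(x0, lagmat(x))
  qr1 <- qr(x1)
  if (qr1$rank < ncol(x1)) return(degenerate)
  rss0 <- sum(qr.resid(qr(x0), resp)^2)
  rss1 <- sum(qr.resid(qr1, resp)^2)
  if (rss1 <= .Machine$double.eps * sum(resp^2)) return(degenerate)
  f <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(statistic = f,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Pairwise Granger causality screen with BH correction
#'
#' Tests both directions of every unordered pair of non-degenerate series
#' and applies the Benjamini-Hochberg correction across all ordered tests;
#' the significant set is `p_adjusted <= alpha`. With very short series
#' (fewer than 10 timepoints) the screen runs but warns that results rest
#' on very few residual degrees of freedom and should be treated carefully.
#'
#' @param series Matrix series x time (e.g. from [prepare_series()]).
#' @param lag Lag order (default 1).
#' @param alpha FDR level for the significant set (default 0.05).
#' @return Data frame of class `granger_result`: driver, target,
#'   statistic, df1, df2, p_raw, p_adjusted, significant, degenerate.
#' @export
granger_all_pairs <- function(series, lag = 1, alpha = 0.05) {
  series <- as.matrix(series)
  degen <- attr(series, "degenerate")
  if (!is.null(degen) && length(degen)) {
    series <- series[setdiff(rownames(series), degen), , drop = FALSE]
  }
  const <- apply(series, 1, function(v) stats::sd(v) == 0)
  if (any(const)) series <- series[!const, , drop = FALSE]
  if (nrow(series) < 2L) {
    stop("at least two non-degenerate series are required", call. = FALSE)
  }
  if (ncol(series) < 10L) {
    warning("only ", ncol(series), " timepoints: lag-", lag,
            " Granger tests have very few residual degrees of freedom; ",
            "treat results carefully", call. = FALSE)
  }
  ids <- rownames(series)
  pairs <- expand.grid(driver = ids, target = ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$driver != pairs$target, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    granger_pair(series[pairs$driver[i], ], series[pairs$target[i], ], lag)
  })
  out <- data.frame(
    driver = pairs$driver,
    target = pairs$target,
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df1 = vapply(res, `[[`, numeric(1), "df1"),
    df2 = vapply(res, `[[`, numeric(1), "df2"),
    p_raw = vapply(res, `[[`, numeric(1), "p_value"),
    degenerate = vapply(res, `[[`, logical(1), "degenerate"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ## BH family: all ordered pairs actually tested (degenerate pairs excluded)
  out$p_adjusted <- NA_real_
  tested <- !out$degenerate
  out$p_adjusted[tested] <- adjust_bh(out$p_raw[tested])
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted <= alpha
  class(out) <- c("granger_result", class(out))
  out
}

#' Export significant Granger pairs as a directed SIF-style edge list
#'
#' @param result A `granger_result` from [granger_all_pairs()].
#' @param path Output TSV.
#' @param significant_only Keep only the BH-significant set
#'   (default `TRUE`).
#' @export
write_granger_sif <- function(result, path, significant_only = TRUE) {
  edges <- if (significant_only) result[result$significant, , drop = FALSE]
           else result
  n <- nrow(edges)
  edges <- data.frame(
    source = edges$driver, target = edges$target,
    weight = edges$statistic, sign = rep_len("+", n),
    provenance = rep_len("granger-lag1", n), directed = rep_len(TRUE, n),
    stringsAsFactors = FALSE
  )
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
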