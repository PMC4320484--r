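#' Sequential K-nearest-neighbour imputation
#'
#' Missing entries are filled feature by feature, in ascending order of
#' missing count (ties by input order). For each incomplete feature the K
#' nearest features from the complete pool are found by Euclidean distance
#' over the feature's observed sample positions (rescaled by
#' `sqrt(n_samples / n_observed)` so distances are comparable across
#' missingness patterns), and each missing entry is filled with the
#' unweighted mean of those K neighbours at that sample. The freshly
#' completed feature then joins the pool and can serve as a neighbour for
#' features imputed later — the "sequential" property of the algorithm.
#' Observed entries are never altered and the procedure is deterministic.
#'
#' @param matrix Numeric matrix (features x samples) with `NA` for missing
#'   entries, or a `feature_matrix`.
#' @param k Number of neighbours (default 10). Must not exceed the number
#'   of complete features available at the start.
#' @return The completed matrix (or `feature_matrix`), with an
#'   `imputation_audit` attribute: data frame of feature, sample, imputed
#'   value and the neighbour IDs used.
#' @examples
#' m <- rbind(A1 = c(1, 2, 3, 4), A2 = c(2, 3, 4, 5),
#'            A3 = c(10, 10, 10, 10), B = c(1.5, 2.5, NA, 4.5))
#' colnames(m) <- paste0("s", 1:4)
#' impute_sknn(m, k = 2)["B", "s3"]  # 3.5
#' @export
impute_sknn <- function(matrix, k = 10) {
  fm <- NULL
  if (inherits(matrix, "feature_matrix")) {
    fm <- matrix
    matrix <- matrix$values
  }
  x <- as.matrix(matrix)
  n_missing <- rowSums(is.na(x))
  if (any(n_missing == ncol(x))) {
    stop("un-imputable: feature(s) fully missing: ",
         paste(rownames(x)[n_missing == ncol(x)], collapse = ", "),
         call. = FALSE)
  }
  if (any(ncol(x) - n_missing < 2 & n_missing > 0)) {
    stop("un-imputable: incomplete feature(s) with fewer than 2 observed values",
         call. = FALSE)
  }
  complete <- which(n_missing == 0L)
  incomplete <- which(n_missing > 0L)
  if (length(incomplete) == 0L) {
    out <- x
  } else {
    if (k < 1 || k > length(complete)) {
      stop("parameter error: `k` must lie between 1 and the number of ",
           "complete features (", length(complete), ")", call. = FALSE)
    }
    audit <- list()
    ## ascending missing count, ties by input order (order() is stable)
    incomplete <- incomplete[order(n_missing[incomplete])]
    pool <- complete
    for (g in incomplete) {
      obs <- which(!is.na(x[g, ]))
      mis <- which(is.na(x[g, ]))
      d2 <- colSums((t(x[pool, obs, drop = FALSE]) - x[g, obs])^2)
      d <- sqrt(d2 * ncol(x) / length(obs))
      nb <- pool[order(d)[seq_len(k)]]  # ties broken by pool order
      fill <- colMeans(x[nb, mis, drop = FALSE])
      x[g, mis] <- fill
      audit[[length(audit) + 1L]] <- data.frame(
        feature_id = rownames(x)[g],
        sample = colnames(x)[mis],
        imputed_value = unname(fill),
        neighbours = paste(rownames(x)[nb], collapse = ","),
        stringsAsFactors = FALSE
      )
      pool <- c(pool, g)
    }
    out <- x
    attr(out, "imputation_audit") <- do.call(rbind, audit)
  }
  if (!is.null(fm)) {
    audit <- attr(out, "imputation_audit")
    attr(out, "imputation_audit") <- NULL
    fm$values <- out
    attr(fm, "imputation_audit") <- audit
    return(fm)
  }
  out
}
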