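#' Log2 transform with half-minimum pseudocount
#'
#' Maps `x` to `log2(x + c)` where `c` is half the smallest positive value
#' of the matrix when zeros are present and 0 otherwise. The transform is
#' strictly increasing, so downstream rank-based tests are unaffected by
#' the base or pseudocount choice.
#'
#' @param x Non-negative numeric matrix (missing values allowed).
#' @return Transformed matrix with a `pseudocount` attribute.
#' @export
log_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) {
    stop("log transform requires non-negative values", call. = FALSE)
  }
  pc <- 0
  if (any(x == 0, na.rm = TRUE)) {
    pos <- x[!is.na(x) & x > 0]
    if (length(pos) == 0L) {
      stop("log transform undefined: no positive values", call. = FALSE)
    }
    pc <- min(pos) / 2
  }
  out <- log2(x + pc)
  attr(out, "pseudocount") <- pc
  out
}

#' Per-feature Kruskal-Wallis tests
#'
#' Runs the tie-corrected Kruskal-Wallis rank-sum test on every feature,
#' with the p-value from the chi-square approximation on `g - 1` degrees of
#' freedom. Features whose values are all identical are flagged degenerate
#' and assigned `p = 1`.
#'
#' @param x Feature x sample matrix (typically log-transformed abundances).
#' @param groups Factor of group labels, one per sample. Every group needs
#'   at least two observations.
#' @param adjust Add Benjamini-Hochberg adjusted p-values across the
#'   features of this call (default `TRUE`).
#' @return Data frame: `feature_id`, `statistic` (H), `df`, `p_raw`,
#'   `p_adjusted`, `degenerate`.
#' @export
kruskal_wallis <- function(x, groups, adjust = TRUE) {
  x <- fm_values(x)
  groups <- droplevels(as.factor(groups))
  check_groups(groups, ncol(x))
  if (nrow(x) == 0L) {
    return(data.frame(feature_id = character(0), statistic = numeric(0),
                      df = numeric(0), p_raw = numeric(0),
                      degenerate = logical(0), p_adjusted = numeric(0)))
  }
  res <- t(apply(x, 1, function(v) {
    ok <- !is.na(v)
    if (length(unique(v[ok])) < 2L) {
      return(c(0, nlevels(groups) - 1L, 1, 1))
    }
    kt <- stats::kruskal.test(v[ok], groups[ok])
    c(unname(kt$statistic), unname(kt$parameter), kt$p.value, 0)
  }))
  out <- data.frame(
    feature_id = rownames(x),
    statistic = res[, 1],
    df = res[, 2],
    p_raw = res[, 3],
    degenerate = res[, 4] == 1,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (adjust) out$p_adjusted <- adjust_bh(out$p_raw)
  out
}

#' Per-feature one-way ANOVA with Tukey HSD and compact letters
#'
#' Fits a one-way fixed-effects ANOVA per feature, runs all pairwise Tukey
#' honest-significant-difference comparisons on the studentized-range
#' distribution, and assembles a compact letter display by
#' insert-and-absorb: two groups share a letter iff their Tukey-adjusted
#' p-value is at least `alpha`. Features with zero variance everywhere are
#' flagged degenerate and get a single shared letter.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Data frame with `feature_id`, `statistic` (F), `df1`, `df2`,
#'   `p_raw`, `p_tukey_min` (smallest pairwise Tukey p), `p_adjusted`
#'   (BH over the ANOVA p-values), `degenerate`, and `letters` (one
#'   `|`-separated string of per-group letters, groups in level order).
#'   The full Tukey p-value matrices are kept in the `tukey` attribute.
#' @export
anova_tukey <- function(x, groups, alpha = 0.05, adjust = TRUE) {
  x <- fm_values(x)
  groups <- droplevels(as.factor(groups))
  check_groups(groups, ncol(x))
  g <- nlevels(groups)
  tukey_all <- vector("list", nrow(x))
  rows <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    ok <- !is.na(v)
    df <- data.frame(v = v[ok], g = groups[ok])
    wvar <- tapply(df$v, df$g, stats::var)
    if (all(wvar == 0, na.rm = TRUE)) {
      all_equal <- length(unique(tapply(df$v, df$g, mean))) == 1L
      rows[[i]] <- data.frame(statistic = 0, df1 = g - 1L,
                              df2 = nrow(df) - g,
                              p_raw = if (all_equal) 1 else 0,
                              p_tukey_min = if (all_equal) 1 else 0,
                              degenerate = TRUE,
                              letters = paste(rep("a", g), collapse = "|"))
      next
    }
    fit <- stats::aov(v ~ g, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    pmat <- tukey_pair_matrix(tk, levels(groups))
    tukey_all[[i]] <- pmat
    letters <- compact_letters(pmat, alpha)
    rows[[i]] <- data.frame(
      statistic = an[["F value"]][1], df1 = an[["Df"]][1],
      df2 = an[["Df"]][2], p_raw = an[["Pr(>F)"]][1],
      p_tukey_min = min(tk[, "p adj"]), degenerate = FALSE,
      letters = paste(letters, collapse = "|")
    )
  }
  out <- cbind(data.frame(feature_id = rownames(x), stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  if (adjust) out$p_adjusted <- adjust_bh(out$p_raw)
  names(tukey_all) <- rownames(x)
  attr(out, "tukey") <- tukey_all
  out
}

#' @keywords internal
check_groups <- function(groups, n_samples) {
  if (length(groups) != n_samples) {
    stop("design error: `groups` must have one label per sample", call. = FALSE)
  }
  if (nlevels(groups) < 2L) {
    stop("design error: at least two groups are required", call. = FALSE)
  }
  if (any(table(groups) < 2L)) {
    stop("design error: every group needs at least two observations",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Symmetric matrix of Tukey-adjusted pairwise p-values
#' @keywords internal
tukey_pair_matrix <- function(tk, lev) {
  pmat <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (r in seq_along(pairs)) {
    a <- pairs[[r]][1]; b <- pairs[[r]][2]
    pmat[a, b] <- pmat[b, a] <- tk[r, "p adj"]
  }
  diag(pmat) <- 1
  pmat
}

#' Compact letter display by insert-and-absorb
#'
#' Starts from one letter covering all groups; every significant pair
#' splits each letter set containing both members into two (insert), and
#' sets that are subsets of another are removed (absorb). The result
#' guarantees two groups share a letter iff no significant difference
#' separates them.
#'
#' @param pmat Symmetric matrix of pairwise adjusted p-values with group
#'   dimnames.
#' @param alpha Significance level.
#' @return Character vector of letter strings, one per group (in the row
#'   order of `pmat`).
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  lev <- rownames(pmat)
  sets <- list(lev)
  for (i in seq_along(lev)[-length(lev)]) {
    for (j in seq((i + 1), length(lev))) {
      if (!is.na(pmat[i, j]) && pmat[i, j] < alpha) {
        new_sets <- list()
        for (s in sets) {
          if (lev[i] %in% s && lev[j] %in% s) {
            new_sets <- c(new_sets, list(setdiff(s, lev[i])),
                          list(setdiff(s, lev[j])))
          } else {
            new_sets <- c(new_sets, list(s))
          }
        }
        ## absorb: drop sets contained in another set
        keep <- rep(TRUE, length(new_sets))
        for (a in seq_along(new_sets)) {
          for (b in seq_along(new_sets)) {
            if (a != b && keep[b] &&
                all(new_sets[[a]] %in% new_sets[[b]]) &&
                (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
              keep[a] <- FALSE
              break
            }
          }
        }
        sets <- new_sets[keep]
      }
    }
  }
  ## deterministic letter order: sets sorted by their first group
  first_idx <- vapply(sets, function(s) min(match(s, lev)), numeric(1))
  sets <- sets[order(first_idx)]
  out <- vapply(lev, function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  unname(out)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment with monotonicity enforcement; input
#' order is preserved.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
adjust_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
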