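#' Percent-of-maximum time profiles
#'
#' Averages replicates per timepoint, then expresses each feature as a
#' percentage of its maximal replicate-mean value over the time series, so
#' every feature attains 100 at its own peak timepoint. All-zero features
#' have no defined maximum; they are excluded and reported in the
#' `excluded` attribute.
#'
#' @param matrix Feature x sample matrix or `feature_matrix` of
#'   non-negative abundances.
#' @param design Sample table.
#' @return Matrix features x timepoints with values in [0, 100].
#' @export
percent_of_max <- function(matrix, design) {
  x <- fm_values(matrix)
  check_design_samples(design, colnames(x))
  x <- x[, design$sample_id, drop = FALSE]
  tp <- sort(unique(design$timepoint))
  means <- vapply(tp, function(t) {
    rowMeans(x[, design$timepoint == t, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) means <- matrix(means, nrow = 1)
  dimnames(means) <- list(rownames(x), as.character(tp))
  mx <- apply(means, 1, max)
  excluded <- rownames(means)[mx <= 0]
  keep <- mx > 0
  out <- 100 * means[keep, , drop = FALSE] / mx[keep]
  attr(out, "excluded") <- excluded
  out
}

#' Aggregate per-feature profiles into functional-bin profiles
#'
#' Restricts the profiles to features passing a significance filter and
#' carrying a bin assignment, then summarizes each bin by the
#' per-timepoint mean and standard deviation of its members'
#' percent-of-max profiles. Features mapping to several bins keep only
#' their first (most specific) assignment. Bins with fewer than two
#' members are kept but flagged.
#'
#' @param profiles Matrix from [percent_of_max()].
#' @param binmap Data frame with columns `feature_id` and `bin` (or a
#'   named character vector feature -> bin).
#' @param significant Optional character vector of feature IDs passing the
#'   univariate threshold; `NULL` keeps all profiled features.
#' @return List with `profile` (long data frame: bin, timepoint, mean, sd,
#'   n_members, small_bin flag) and `unmapped` (significant features
#'   without a bin).
#' @export
bin_aggregate <- function(profiles, binmap, significant = NULL) {
  if (!is.data.frame(binmap)) {
    binmap <- data.frame(feature_id = names(binmap), bin = unname(binmap),
                         stringsAsFactors = FALSE)
  }
  if (nrow(binmap) == 0L) stop("`binmap` is empty", call. = FALSE)
  binmap <- binmap[!duplicated(binmap$feature_id), , drop = FALSE]
  keep <- rownames(profiles)
  if (!is.null(significant)) keep <- intersect(keep, significant)
  unmapped <- setdiff(keep, binmap$feature_id)
  keep <- intersect(keep, binmap$feature_id)
  if (length(keep) == 0L) {
    return(list(profile = data.frame(bin = character(0), timepoint = numeric(0),
                                     mean = numeric(0), sd = numeric(0),
                                     n_members = integer(0),
                                     small_bin = logical(0)),
                unmapped = unmapped))
  }
  bins <- binmap$bin[match(keep, binmap$feature_id)]
  tp <- as.numeric(colnames(profiles))
  rows <- lapply(sort(unique(bins)), function(b) {
    members <- profiles[keep[bins == b], , drop = FALSE]
    data.frame(bin = b, timepoint = tp,
               mean = colMeans(members),
               sd = apply(members, 2, stats::sd),
               n_members = nrow(members),
               small_bin = nrow(members) < 2L,
               stringsAsFactors = FALSE)
  })
  list(profile = do.call(rbind, rows), unmapped = unmapped)
}

#' Bicluster a summary matrix over rows and columns
#'
#' Agglomerative hierarchical clustering of the rows and of the columns of
#' a (bin or feature) x timepoint matrix. Distance and linkage default to
#' Euclidean/complete. Leaf ordering is the deterministic `hclust` order
#' (ties resolved by input order through the stable distance ordering).
#'
#' @param m Numeric matrix, at least 2 x 2, without missing values.
#' @param distance Distance measure passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with the reordered `matrix`, `row_hclust`, `col_hclust`,
#'   `row_order`, `col_order` and the merge `heights` of both dendrograms.
#' @export
bicluster_heatmap <- function(m, distance = "euclidean", linkage = "complete") {
  m <- as.matrix(m)
  if (anyNA(m)) stop("input contains missing values", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("at least 2 rows and 2 columns are required", call. = FALSE)
  }
  row_hc <- stats::hclust(stats::dist(m, method = distance), method = linkage)
  col_hc <- stats::hclust(stats::dist(t(m), method = distance), method = linkage)
  list(matrix = m[row_hc$order, col_hc$order, drop = FALSE],
       row_hclust = row_hc, col_hclust = col_hc,
       row_order = row_hc$order, col_order = col_hc$order,
       heights = list(rows = row_hc$height, cols = col_hc$height))
}

#' Serialize a dendrogram as a Newick string
#'
#' @param hc An `hclust` object.
#' @return Newick string (branch lengths from merge heights).
#' @export
as_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
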