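#' Normalized spectral abundance factor (NSAF)
#'
#' For protein k in a sample, `NSAF_k = (PSM_k / L_k) / sum_i (PSM_i / L_i)`:
#' the spectral count divided by the protein length, normalized to the sum
#' of that ratio over all proteins in the sample. Columns therefore sum to
#' one and NSAF is a dimensionless relative abundance in [0, 1].
#'
#' @param counts A `spectral_counts` object, or a numeric matrix of PSM
#'   counts (proteins x samples) if `lengths` is given.
#' @param lengths Protein lengths in residues (ignored when `counts` is a
#'   `spectral_counts` object).
#' @return Matrix of NSAF values with the same dimnames as the counts.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_nsaf(m, lengths = c(100, 200))  # 2/3 and 1/3
#' @export
compute_nsaf <- function(counts, lengths = NULL) {
  if (inherits(counts, "spectral_counts")) {
    lengths <- counts$length
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lengths) || length(lengths) != nrow(counts)) {
    stop("`lengths` must give one protein length per row", call. = FALSE)
  }
  if (any(lengths < 1)) stop("protein lengths must be >= 1", call. = FALSE)
  if (any(counts < 0, na.rm = TRUE)) stop("PSM counts must be >= 0", call. = FALSE)
  saf <- counts / lengths
  tot <- colSums(saf)
  bad <- which(tot == 0)
  if (length(bad)) {
    stop("degenerate sample(s) with all-zero spectral counts: ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  }
  sweep(saf, 2, tot, "/")
}

#' Minimum-abundance filter
#'
#' Retains proteins whose NSAF reaches `tau` (default 0.001). The summary
#' the threshold is applied to is configurable: `"max"` (default) keeps a
#' protein if its maximum NSAF over samples reaches `tau`, which retains
#' stage-specific proteins detectable only under starvation; `"mean"` uses
#' the mean over samples; `"all_samples"` requires every sample to reach
#' `tau`. Row order is preserved.
#'
#' @param nsaf NSAF matrix from [compute_nsaf()].
#' @param tau Minimum abundance (> 0).
#' @param rule Summary the threshold applies to.
#' @return The filtered matrix, with a `filter_report` attribute
#'   (data frame: feature, summary value, retained flag).
#' @export
filter_min_abundance <- function(nsaf, tau = 0.001,
                                 rule = c("max", "mean", "all_samples")) {
  rule <- match.arg(rule)
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  summ <- switch(rule,
                 max = apply(nsaf, 1, max, na.rm = TRUE),
                 mean = rowMeans(nsaf, na.rm = TRUE),
                 all_samples = apply(nsaf, 1, min, na.rm = TRUE))
  keep <- summ >= tau
  out <- nsaf[keep, , drop = FALSE]
  attr(out, "filter_report") <- data.frame(
    feature_id = rownames(nsaf), summary = summ, retained = keep,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Replicate-presence filter for proteins
#'
#' A feature is retained iff it is detected (strictly positive, non-missing)
#' in all replicates of at least one timepoint, or its detections span at
#' least `alt_times` distinct timepoints (`alt_rule = "distinct_times"`,
#' the default reading of "five samples corresponding to different times");
#' `alt_rule = "any_samples"` instead accepts `alt_times` detections
#' anywhere.
#'
#' @param matrix Feature x sample matrix; columns must match the design.
#' @param design Sample table from [generate_design()].
#' @param n_required Replicates required at a single timepoint (default:
#'   all replicates present at that timepoint).
#' @param alt_times Fallback threshold (default 5).
#' @param alt_rule How the fallback clause counts detections.
#' @return Filtered matrix with a `filter_report` attribute (feature,
#'   which clause was satisfied, retained flag).
#' @export
filter_replicate_presence <- function(matrix, design, n_required = NULL,
                                      alt_times = 5,
                                      alt_rule = c("distinct_times", "any_samples")) {
  alt_rule <- match.arg(alt_rule)
  check_design_samples(design, colnames(matrix))
  matrix <- matrix[, design$sample_id, drop = FALSE]
  detected <- !is.na(matrix) & matrix > 0
  tp <- factor(design$timepoint)
  reps_per_tp <- table(tp)
  det_per_tp <- detections_per_timepoint(detected, tp)
  need <- if (is.null(n_required)) as.vector(reps_per_tp) else {
    if (any(n_required > reps_per_tp)) {
      stop("`n_required` exceeds the replicate count of a timepoint", call. = FALSE)
    }
    rep(n_required, nlevels(tp))
  }
  clause_reps <- if (nrow(matrix) == 0L) logical(0) else
    rowSums(det_per_tp >= matrix(need, nrow(matrix), nlevels(tp),
                                 byrow = TRUE)) > 0
  clause_alt <- switch(alt_rule,
                       distinct_times = rowSums(det_per_tp > 0) >= alt_times,
                       any_samples = rowSums(detected) >= alt_times)
  keep <- clause_reps | clause_alt
  out <- matrix[keep, , drop = FALSE]
  attr(out, "filter_report") <- data.frame(
    feature_id = rownames(matrix),
    all_replicates_one_time = unname(clause_reps),
    fallback_clause = unname(clause_alt),
    retained = unname(keep),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Sample-centric normalization of metabolite peak areas
#'
#' Divides each peak area by the total peak area of its sample, so each
#' sample column sums to one.
#'
#' @param peaks Metabolite x sample matrix of non-negative peak areas
#'   (missing values allowed; totals use observed values).
#' @return Normalized matrix.
#' @export
normalize_metabolites <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (any(peaks < 0, na.rm = TRUE)) {
    stop("peak areas must be non-negative", call. = FALSE)
  }
  tot <- colSums(peaks, na.rm = TRUE)
  bad <- which(tot <= 0)
  if (length(bad)) {
    stop("degenerate sample(s) with zero total peak area: ",
         paste(colnames(peaks)[bad], collapse = ", "), call. = FALSE)
  }
  sweep(peaks, 2, tot, "/")
}

#' Presence filter for metabolites
#'
#' A metabolite is retained iff it is detected in all replicates of at
#' least one timepoint, or in strictly more than `min_samples` samples
#' overall (any timepoints).
#'
#' @inheritParams filter_replicate_presence
#' @param min_samples Strict lower bound for the fallback clause
#'   (default 18).
#' @return Filtered matrix with a `filter_report` attribute.
#' @export
filter_metabolite_presence <- function(matrix, design, n_required = NULL,
                                       min_samples = 18) {
  check_design_samples(design, colnames(matrix))
  matrix <- matrix[, design$sample_id, drop = FALSE]
  detected <- !is.na(matrix) & matrix > 0
  tp <- factor(design$timepoint)
  reps_per_tp <- table(tp)
  det_per_tp <- detections_per_timepoint(detected, tp)
  need <- if (is.null(n_required)) as.vector(reps_per_tp) else rep(n_required, nlevels(tp))
  clause_reps <- if (nrow(matrix) == 0L) logical(0) else
    rowSums(det_per_tp >= matrix(need, nrow(matrix), nlevels(tp),
                                 byrow = TRUE)) > 0
  clause_alt <- rowSums(detected) > min_samples
  keep <- clause_reps | clause_alt
  out <- matrix[keep, , drop = FALSE]
  attr(out, "filter_report") <- data.frame(
    feature_id = rownames(matrix),
    all_replicates_one_time = unname(clause_reps),
    fallback_clause = unname(clause_alt),
    retained = unname(keep),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Normalize physiological variables to their T0 baseline
#'
#' Flagged variables are divided by their mean over the first-timepoint
#' replicates, expressing them as fold change relative to the unstressed
#' control; unflagged variables (e.g. Fv/Fm, which is already a ratio) pass
#' through unchanged.
#'
#' @param values Variable x sample matrix.
#' @param design Sample table.
#' @param normalize Character vector of variable names to normalize
#'   (default: every variable except `"FvFm"`).
#' @return Matrix of the same shape.
#' @export
normalize_physio_t0 <- function(values, design,
                                normalize = setdiff(rownames(values), "FvFm")) {
  check_design_samples(design, colnames(values))
  values <- values[, design$sample_id, drop = FALSE]
  t0 <- design$sample_id[design$timepoint == min(design$timepoint)]
  out <- values
  for (v in intersect(normalize, rownames(values))) {
    base <- mean(values[v, t0], na.rm = TRUE)
    if (!is.finite(base) || base == 0) {
      stop("degenerate baseline: T0 mean of `", v, "` is zero or undefined",
           call. = FALSE)
    }
    out[v, ] <- values[v, ] / base
  }
  out
}

#' Merge protein, metabolite and physiology blocks into one feature matrix
#'
#' Rows are stacked with block-prefixed feature IDs (`protein:`,
#' `metabolite:`, `physiology:`) so IDs are globally unique; columns are
#' aligned to the design order. All blocks must cover the identical sample
#' set.
#'
#' @param proteins,metabolites,physio Feature x sample matrices (any may
#'   have zero rows).
#' @param design Sample table.
#' @return A `feature_matrix` object: list with `values` (stacked matrix),
#'   `blocks` (factor per row) and `design`.
#' @export
merge_blocks <- function(proteins, metabolites, physio, design) {
  blocks <- list(protein = proteins, metabolite = metabolites,
                 physiology = physio)
  blocks <- Filter(function(m) !is.null(m) && nrow(m) > 0, blocks)
  for (b in names(blocks)) check_design_samples(design, colnames(blocks[[b]]))
  stacked <- do.call(rbind, lapply(names(blocks), function(b) {
    m <- blocks[[b]][, design$sample_id, drop = FALSE]
    rownames(m) <- paste0(b, ":", rownames(m))
    m
  }))
  labels <- factor(sub(":.*$", "", rownames(stacked)),
                   levels = c("protein", "metabolite", "physiology"))
  structure(
    list(values = stacked, blocks = labels, design = design),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", nrow(x$values), " features x ", ncol(x$values),
      " samples (", paste(sprintf("%s: %d", levels(x$blocks), table(x$blocks)),
                          collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Detection counts per timepoint, robust to 0- or 1-row inputs
#' @keywords internal
detections_per_timepoint <- function(detected, tp) {
  out <- vapply(levels(tp), function(l) {
    rowSums(detected[, tp == l, drop = FALSE])
  }, numeric(nrow(detected)))
  if (nrow(detected) == 1L) {
    out <- matrix(out, nrow = 1L,
                  dimnames = list(rownames(detected), levels(tp)))
  }
  out
}

#' Extract the numeric values of a feature matrix (or pass a matrix through)
#' @param x A `feature_matrix` or numeric matrix.
#' @keywords internal
fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}
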