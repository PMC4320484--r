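#' Write a feature-by-sample table as TSV
#'
#' Features in rows, samples in columns, first column the feature ID.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file.
#' @param id_name Name of the ID column.
#' @param extra Optional data frame of per-feature columns inserted after
#'   the ID (e.g. protein length).
#' @export
write_feature_tsv <- function(x, path, id_name = "feature_id", extra = NULL) {
  df <- data.frame(id = rownames(x), stringsAsFactors = FALSE)
  names(df) <- id_name
  if (!is.null(extra)) df <- cbind(df, extra)
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV back into a matrix
#'
#' @param path TSV written by [write_feature_tsv()].
#' @param meta_cols Names of non-sample columns (beyond the first ID
#'   column) to return separately.
#' @return List with `values` (matrix) and `meta` (data frame of
#'   `meta_cols`, possibly empty).
#' @export
read_feature_tsv <- function(path, meta_cols = character(0)) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  meta <- df[, intersect(meta_cols, names(df)), drop = FALSE]
  vals <- as.matrix(df[, setdiff(names(df)[-1], meta_cols), drop = FALSE])
  rownames(vals) <- ids
  rownames(meta) <- ids
  list(values = vals, meta = meta)
}

#' Write a synthetic study to disk
#'
#' Writes the five input tables as TSV (proteome with a `length` column),
#' the ground-truth record as JSON, and a run log recording the seed.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param params The [sim_params()] used (recorded in the run log).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_tsv(study$proteome$counts, file.path(dir, "proteome_psm.tsv"),
                    id_name = "protein_id",
                    extra = data.frame(length = study$proteome$length))
  write_feature_tsv(study$metabolites, file.path(dir, "metabolite_peaks.tsv"),
                    id_name = "metabolite_id")
  write_feature_tsv(study$physio, file.path(dir, "physiology.tsv"),
                    id_name = "variable")
  utils::write.table(study$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_feature_tsv(study$series, file.path(dir, "causal_series.tsv"),
                    id_name = "series_id")

  truth <- study$truth
  truth_json <- list(
    responders = truth$responders,
    profiles = as.data.frame(truth$profiles),
    block_memberships = as.list(truth$block_memberships),
    causal_pairs = truth$causal_pairs,
    sample_groups = stats::setNames(as.list(truth$sample_groups),
                                    study$design$sample_id),
    starved_timepoints = truth$starved_timepoints,
    missing_cells = which(truth$missing_mask, arr.ind = TRUE) |>
      (\(m) data.frame(feature = rownames(truth$missing_mask)[m[, 1]],
                       sample = colnames(truth$missing_mask)[m[, 2]]))(),
    seed = truth$seed
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- list(seed = truth$seed,
              n_samples = nrow(study$design),
              params = if (is.null(params)) NULL else unclass(params))
  jsonlite::write_json(log, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the study tables back from disk
#'
#' @param dir Directory written by [write_study()].
#' @return List with `design`, `proteome` (`spectral_counts`),
#'   `metabolites`, `physio` and `series`.
#' @export
read_study <- function(dir) {
  design <- utils::read.delim(file.path(dir, "design.tsv"),
                              stringsAsFactors = FALSE)
  prot <- read_feature_tsv(file.path(dir, "proteome_psm.tsv"),
                           meta_cols = "length")
  proteome <- structure(
    list(counts = prot$values,
         length = stats::setNames(prot$meta$length, rownames(prot$values)),
         design = design),
    class = "spectral_counts"
  )
  list(
    design = design,
    proteome = proteome,
    metabolites = read_feature_tsv(file.path(dir, "metabolite_peaks.tsv"))$values,
    physio = read_feature_tsv(file.path(dir, "physiology.tsv"))$values,
    series = read_feature_tsv(file.path(dir, "causal_series.tsv"))$values
  )
}
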