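#' Describe a time-course sampling design
#'
#' A design is a set of strictly increasing sampling times (hours) with a
#' fixed number of biological replicates per timepoint. The default matches
#' the nitrogen-starvation/recovery layout the package emulates: controls at
#' 0 h, starvation samples at 5, 24 and 72 h, and recovery samples 5 h and
#' 24 h after nutrient replenishment (77 and 96 h), each with four
#' biological replicates.
#'
#' @param timepoints Numeric vector of sampling times in hours, strictly
#'   increasing.
#' @param n_replicates Number of biological replicates per timepoint
#'   (a single positive integer).
#' @param seed Integer RNG seed recorded with the design and used as the
#'   base seed by the simulators.
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' generate_design(spec)
#' @export
design_spec <- function(timepoints = c(0, 5, 24, 72, 77, 96),
                        n_replicates = 4,
                        seed = 1L) {
  if (!is.numeric(timepoints) || length(timepoints) < 1L || anyNA(timepoints)) {
    stop("`timepoints` must be a non-empty numeric vector", call. = FALSE)
  }
  if (length(timepoints) > 1L && any(diff(timepoints) <= 0)) {
    stop("invalid design: `timepoints` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(n_replicates) || length(n_replicates) != 1L ||
      is.na(n_replicates) || n_replicates < 1 || n_replicates != round(n_replicates)) {
    stop("invalid design: `n_replicates` must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      timepoints = as.numeric(timepoints),
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "design_spec"
  )
}

#' Expand a design into a sample table
#'
#' @param spec A [design_spec()] object (or a list coercible to one).
#' @return A data frame with one row per sample and columns `sample_id`
#'   (of the form `T<hours>_R<replicate>`), `timepoint` and `replicate`.
#'   Sample IDs are deterministic functions of the design.
#' @export
generate_design <- function(spec = design_spec()) {
  if (!inherits(spec, "design_spec")) {
    spec <- do.call(design_spec, as.list(spec))
  }
  tp <- rep(spec$timepoints, each = spec$n_replicates)
  rep_idx <- rep(seq_len(spec$n_replicates), times = length(spec$timepoints))
  data.frame(
    sample_id = sprintf("T%s_R%d", format(tp, trim = TRUE, scientific = FALSE), rep_idx),
    timepoint = tp,
    replicate = rep_idx,
    stringsAsFactors = FALSE
  )
}

#' Validate that a design table covers a set of sample columns
#'
#' @param design Sample table as returned by [generate_design()].
#' @param sample_ids Character vector of sample names to check.
#' @keywords internal
check_design_samples <- function(design, sample_ids) {
  missing_in_design <- setdiff(sample_ids, design$sample_id)
  missing_in_data <- setdiff(design$sample_id, sample_ids)
  if (length(missing_in_design) || length(missing_in_data)) {
    stop(
      "design/sample mismatch: ",
      if (length(missing_in_design)) {
        paste0("samples absent from design: ",
               paste(missing_in_design, collapse = ", "), "; ")
      } else "",
      if (length(missing_in_data)) {
        paste0("design samples absent from data: ",
               paste(missing_in_data, collapse = ", "))
      } else "",
      call. = FALSE
    )
  }
  invisible(TRUE)
}
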