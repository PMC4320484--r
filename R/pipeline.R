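#' Default pipeline configuration
#'
#' Every stage parameter of the pipeline with its recorded default. The
#' configuration round-trips losslessly to the JSON run log.
#'
#' @param seed Global seed; per-stage seeds are derived deterministically
#'   from it.
#' @return Nested list of stage parameters.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    inputs = NULL,          # directory of study TSVs; NULL simulates
    sim = list(),           # sim_params() overrides when simulating
    quantify = list(tau = 0.001, abundance_rule = "max", alt_times = 5,
                    metabolite_min_samples = 18, physio_t0_exempt = "FvFm"),
    impute = list(k = 10),
    univariate = list(alpha = 0.05),
    latent = list(ncomp = 3, keepX = 50),
    network = list(similarity_cutoff = 0.9, correlation_cutoff = 0.9,
                   correlation_method = "pearson"),
    granger = list(lag = 1, alpha = 0.05, features = "significant"),
    profiles = list(distance = "euclidean", linkage = "complete")
  )
}

#' Merge user configuration over the defaults
#' @keywords internal
merge_config <- function(config) {
  base <- default_config(if (is.null(config$seed)) 1L else config$seed)
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]])) {
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  base
}

#' Synthetic functional-bin map from a simulation truth record
#'
#' Assigns planted responders to direction-by-phase bins (induced/repressed
#' during deep starvation vs the replete phase, emulating functional
#' categories that respond coherently to nutrient status) and latent-block
#' members to per-factor bins; all other features stay unmapped, mirroring
#' the unannotated fraction of a real proteome.
#'
#' @param truth Truth record from [simulate_study()].
#' @return Data frame with `feature_id` (block-prefixed) and `bin`.
#' @export
synthetic_bin_map <- function(truth) {
  rows <- list()
  if (nrow(truth$responders)) {
    ## bins emulate functional categories responding coherently to the
    ## nutrient status: direction x phase (deep starvation vs replete)
    phase <- ifelse(truth$responders$peak_time %in% truth$starved_timepoints,
                    "starvation", "replete")
    rows$resp <- data.frame(
      feature_id = paste0("protein:", truth$responders$feature_id),
      bin = sprintf("%s.%s", truth$responders$direction, phase),
      stringsAsFactors = FALSE
    )
  }
  blocks <- truth$block_memberships
  if (length(blocks)) {
    rows$blocks <- data.frame(
      feature_id = names(blocks),
      bin = sprintf("latent_block.F%d", blocks),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full quantification-to-network pipeline
#'
#' Executes the fixed stage order quantify -> impute -> univariate ->
#' latent -> network -> causality -> profiles on either a simulated study
#' (default) or tables read from `config$inputs`, writing every
#' intermediate table plus a JSON run log when `outdir` is given. Any
#' stage error aborts with the stage name; partial outputs are retained
#' next to a `FAILED` marker naming the stage.
#'
#' @param config Configuration list (see [default_config()]); missing
#'   entries take their defaults.
#' @param outdir Output directory, or `NULL` to skip writing.
#' @return A run report: list with the filtered matrices, statistics
#'   tables, latent models, networks, Granger results, profiles, the
#'   truth record (when simulated) and the `counts` log of features
#'   surviving each filter.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  config <- merge_config(config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    unlink(file.path(outdir, "FAILED"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) {
        writeLines(paste0("FAILED at stage: ", name, "\n", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      }
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  counts <- list()
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    msg
  }

  ## ---- inputs -------------------------------------------------------
  truth <- NULL
  study <- stage("inputs", {
    if (!is.null(config$inputs)) {
      if (!dir.exists(config$inputs)) {
        stop("input directory not found: ", config$inputs)
      }
      read_study(config$inputs)
    } else {
      params <- do.call(sim_params, c(config$sim, list(seed = config$seed)))
      s <- simulate_study(params, seed = config$seed)
      truth <- s$truth
      s
    }
  })
  design <- study$design
  counts$n_samples <- nrow(design)
  counts$proteins_input <- nrow(study$proteome$counts)
  counts$metabolites_input <- nrow(study$metabolites)

  ## ---- quantify -----------------------------------------------------
  q <- config$quantify
  quant <- stage("quantify", {
    nsaf <- compute_nsaf(study$proteome)
    nsaf_ab <- filter_min_abundance(nsaf, tau = q$tau, rule = q$abundance_rule)
    nsaf_f <- filter_replicate_presence(nsaf_ab, design, alt_times = q$alt_times)
    met_f <- filter_metabolite_presence(study$metabolites, design,
                                        min_samples = q$metabolite_min_samples)
    phys <- study$physio
    if (nrow(phys)) {
      phys <- normalize_physio_t0(phys, design,
                                  normalize = setdiff(rownames(phys),
                                                      q$physio_t0_exempt))
    }
    list(nsaf = nsaf_f, n_after_abundance = nrow(nsaf_ab),
         metabolites_raw = met_f, physio = phys)
  })
  counts$proteins_after_abundance <- quant$n_after_abundance
  counts$proteins_after_presence <- nrow(quant$nsaf)
  counts$metabolites_after_presence <- nrow(quant$metabolites_raw)

  ## nothing left to analyse: record the filter outcome and stop cleanly
  if (nrow(quant$nsaf) == 0L || nrow(quant$metabolites_raw) == 0L) {
    note("pipeline stopped after quantify: no features survived the filters")
    report <- list(config = config, design = design, counts = counts,
                   quantified = list(nsaf = quant$nsaf,
                                     metabolites = quant$metabolites_raw,
                                     physio = quant$physio),
                   truth = truth, warnings = warnings_log)
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(seed = config$seed, parameters = config, counts = counts,
             warnings = warnings_log),
        file.path(outdir, "run_log.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    }
    warning("no features survived the filters; returning a partial report",
            call. = FALSE)
    return(invisible(report))
  }

  ## ---- impute -------------------------------------------------------
  imp <- stage("impute", {
    met <- quant$metabolites_raw
    n_missing <- sum(is.na(met))
    if (n_missing > 0) {
      ## impute on the log scale (the scale the KNN distance is meaningful
      ## on for abundance data), then back-transform
      lg <- log_transform(met)
      pc <- attr(lg, "pseudocount")
      filled <- impute_sknn(lg, k = min(config$impute$k,
                                        sum(rowSums(is.na(lg)) == 0)))
      met <- 2^filled - pc
    }
    list(metabolites_raw = met, n_imputed = n_missing)
  })
  counts$imputed_cells <- imp$n_imputed
  met_norm <- stage("quantify", normalize_metabolites(imp$metabolites_raw))

  ## ---- univariate ---------------------------------------------------
  groups <- factor(design$timepoint)
  alpha <- config$univariate$alpha
  uni <- stage("univariate", {
    prot_log <- log_transform(quant$nsaf)
    kw <- kruskal_wallis(prot_log, groups)
    met_stats <- anova_tukey(log_transform(met_norm), groups, alpha = alpha)
    phys_stats <- if (nrow(quant$physio) >= 1)
      anova_tukey(quant$physio, groups, alpha = alpha) else NULL
    list(proteins = kw, metabolites = met_stats, physio = phys_stats,
         prot_log = prot_log)
  })
  counts$proteins_significant <- sum(uni$proteins$p_adjusted <= alpha)
  counts$metabolites_significant <- sum(uni$metabolites$p_adjusted <= alpha)

  ## ---- latent -------------------------------------------------------
  lat <- stage("latent", {
    merged <- merge_blocks(uni$prot_log, log_transform(met_norm),
                           quant$physio, design)
    xall <- autoscale(t(merged$values))
    pca_model <- pca(xall, ncomp = min(config$latent$ncomp,
                                       nrow(xall) - 1L, ncol(xall)))
    plsda_model <- plsda(xall, groups, ncomp = min(config$latent$ncomp,
                                                   nrow(xall) - 1L))
    pred <- merge_blocks(uni$prot_log, log_transform(met_norm),
                         matrix(numeric(0), 0, nrow(design),
                                dimnames = list(NULL, design$sample_id)),
                         design)
    xs <- autoscale(t(pred$values))
    spls_model <- NULL
    ys <- NULL
    if (nrow(quant$physio) >= 1) {
      phys_mat <- quant$physio
      rownames(phys_mat) <- paste0("physiology:", rownames(phys_mat))
      ys <- autoscale(t(phys_mat))
      spls_model <- spls(xs, ys,
                         ncomp = min(config$latent$ncomp, nrow(xs) - 1L),
                         keepX = min(config$latent$keepX, ncol(xs)))
    }
    list(merged = merged, x_all = xall, x_pred = xs, y_phys = ys,
         pca = pca_model, plsda = plsda_model, spls = spls_model)
  })

  ## ---- network ------------------------------------------------------
  blocks_vec <- stats::setNames(as.character(lat$merged$blocks),
                                rownames(lat$merged$values))
  nw <- config$network
  net <- stage("network", {
    nets <- list()
    if (!is.null(lat$spls)) {
      sim <- spls_similarity(lat$spls, lat$x_pred, lat$y_phys)
      nets$spls <- threshold_network(sim, nw$similarity_cutoff, blocks_vec,
                                     provenance = "spls-similarity")
    }
    cc <- pairwise_correlation(lat$x_pred |> t(),
                               method = nw$correlation_method)
    nets$correlation <- threshold_network(cc, nw$correlation_cutoff,
                                          blocks_vec,
                                          provenance = "pairwise-correlation")
    combined <- if (!is.null(nets$spls)) {
      merge_networks(nets$spls, nets$correlation)
    } else nets$correlation
    c(nets, list(combined = combined))
  })
  counts$network_nodes <- nrow(net$combined$nodes)
  counts$network_edges <- nrow(net$combined$edges)

  ## ---- causality ----------------------------------------------------
  gr <- config$granger
  granger <- stage("causality", {
    feats <- rownames(lat$merged$values)
    if (identical(gr$features, "significant")) {
      sig <- c(
        paste0("protein:",
               uni$proteins$feature_id[uni$proteins$p_adjusted <= alpha]),
        paste0("metabolite:",
               uni$metabolites$feature_id[uni$metabolites$p_adjusted <= alpha]),
        paste0("physiology:", rownames(quant$physio))
      )
      feats <- intersect(feats, sig)
    }
    if (length(feats) < 2L) {
      note("causality skipped: fewer than two eligible series")
      NULL
    } else {
      series <- prepare_series(lat$merged$values[feats, , drop = FALSE], design)
      withCallingHandlers(
        granger_all_pairs(series, lag = gr$lag, alpha = gr$alpha),
        warning = function(w) {
          note("granger: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
  })
  if (!is.null(granger)) {
    counts$granger_tested <- sum(!granger$degenerate)
    counts$granger_significant <- sum(granger$significant)
  }

  ## ---- profiles -----------------------------------------------------
  pr <- config$profiles
  profiles <- stage("profiles", {
    prof <- percent_of_max(quant$nsaf, design)
    rownames(prof) <- paste0("protein:", rownames(prof))
    binmap <- if (!is.null(config$binmap)) config$binmap
              else if (!is.null(truth)) synthetic_bin_map(truth) else NULL
    sig <- paste0("protein:",
                  uni$proteins$feature_id[uni$proteins$p_adjusted <= alpha])
    bins <- if (!is.null(binmap)) bin_aggregate(prof, binmap, sig) else NULL
    heat <- NULL
    if (!is.null(bins) && nrow(bins$profile)) {
      bm <- stats::reshape(bins$profile[, c("bin", "timepoint", "mean")],
                           idvar = "bin", timevar = "timepoint",
                           direction = "wide")
      rn <- bm$bin
      bm <- as.matrix(bm[, -1, drop = FALSE])
      dimnames(bm) <- list(rn, sort(unique(bins$profile$timepoint)))
      if (nrow(bm) >= 2L && ncol(bm) >= 2L) {
        heat <- bicluster_heatmap(bm, distance = pr$distance,
                                  linkage = pr$linkage)
      }
    }
    list(percent_of_max = prof, bins = bins, heatmap = heat)
  })

  ## ---- outputs ------------------------------------------------------
  report <- list(config = config, design = design, counts = counts,
                 quantified = list(nsaf = quant$nsaf,
                                   metabolites = met_norm,
                                   physio = quant$physio),
                 univariate = uni[c("proteins", "metabolites", "physio")],
                 latent = lat[c("pca", "plsda", "spls")],
                 networks = net, granger = granger, profiles = profiles,
                 truth = truth, warnings = warnings_log)
  if (!is.null(outdir)) {
    stage("outputs", write_run_outputs(report, outdir))
  }
  invisible(report)
}

#' @keywords internal
write_run_outputs <- function(report, outdir) {
  write_feature_tsv(report$quantified$nsaf,
                    file.path(outdir, "nsaf_filtered.tsv"), "protein_id")
  write_feature_tsv(report$quantified$metabolites,
                    file.path(outdir, "metabolites_normalized.tsv"),
                    "metabolite_id")
  if (nrow(report$quantified$physio)) {
    write_feature_tsv(report$quantified$physio,
                      file.path(outdir, "physiology_normalized.tsv"),
                      "variable")
  }
  for (b in c("proteins", "metabolites", "physio")) {
    tb <- report$univariate[[b]]
    if (!is.null(tb)) {
      utils::write.table(tb, file.path(outdir, paste0("stats_", b, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (m in c("pca", "plsda", "spls")) {
    if (!is.null(report$latent[[m]])) {
      write_latent_model(report$latent[[m]], outdir, prefix = m)
    }
  }
  write_sif(report$networks$combined, file.path(outdir, "network_edges.sif"))
  write_graphml(report$networks$combined, file.path(outdir, "network.graphml"))
  if (!is.null(report$granger)) {
    utils::write.table(report$granger, file.path(outdir, "granger.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_granger_sif(report$granger, file.path(outdir, "granger_edges.sif"))
  }
  write_feature_tsv(report$profiles$percent_of_max,
                    file.path(outdir, "profiles_percent_of_max.tsv"))
  if (!is.null(report$profiles$bins)) {
    utils::write.table(report$profiles$bins$profile,
                       file.path(outdir, "bin_profiles.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$profiles$heatmap)) {
    write_feature_tsv(report$profiles$heatmap$matrix,
                      file.path(outdir, "heatmap_matrix.tsv"), "bin")
    writeLines(c(as_newick(report$profiles$heatmap$row_hclust),
                 as_newick(report$profiles$heatmap$col_hclust)),
               file.path(outdir, "dendrograms.nwk"))
  }
  log <- list(seed = report$config$seed, parameters = report$config,
              counts = report$counts, warnings = report$warnings)
  jsonlite::write_json(log, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
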