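#' Relevance-network similarity from a fitted sPLS model
#'
#' The standard relevance-network construction for regression-mode sPLS:
#' `sim(i, j) = sum_h cor(x_i, t_h) * cor(y_j, t_h)` over the fitted
#' components' X-scores `t_h`. Values are clipped to [-1, 1]; clip events
#' are counted in the `clipped` attribute.
#'
#' @param model Fitted [spls()] model (scores stored).
#' @param x,y The data matrices the model was fitted on (samples x
#'   features; correlations are scale-invariant so raw or autoscaled data
#'   give the same result).
#' @return Bipartite association matrix, X-features x Y-features.
#' @export
spls_similarity <- function(model, x, y) {
  if (!inherits(model, "latent_model") || is.null(model$scores)) {
    stop("state error: `model` must be a fitted latent model with scores",
         call. = FALSE)
  }
  cx <- stats::cor(as.matrix(x), model$scores)
  cy <- stats::cor(as.matrix(y), model$scores)
  sim <- tcrossprod(cx, cy)
  n_clip <- sum(sim > 1 | sim < -1)
  sim <- pmin(pmax(sim, -1), 1)
  attr(sim, "clipped") <- n_clip
  sim
}

#' Pairwise feature-feature correlation matrix
#'
#' @param matrix Feature x sample matrix or `feature_matrix`.
#' @param method `"pearson"` or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal. Constant
#'   features have undefined correlations, which are recorded as `NA`
#'   (producing no edges downstream) with a warning.
#' @export
pairwise_correlation <- function(matrix, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- fm_values(matrix)
  if (ncol(x) < 3L) {
    stop("at least 3 samples are required for correlations", call. = FALSE)
  }
  const <- apply(x, 1, function(v) stats::sd(v, na.rm = TRUE) == 0)
  if (any(const)) {
    warning("constant feature(s) have undefined correlations: ",
            paste(rownames(x)[const], collapse = ", "), call. = FALSE)
  }
  suppressWarnings(cc <- stats::cor(t(x), method = method,
                                    use = "pairwise.complete.obs"))
  diag(cc) <- 1
  cc
}

#' Threshold an association matrix into a network
#'
#' Keeps edges with `|association| >= cutoff`. Square symmetric inputs
#' yield an undirected feature-feature network (upper triangle scanned
#' once, no self-edges); rectangular inputs yield a bipartite network over
#' row and column features. Edges below the cutoff are absent, not
#' zero-weighted.
#'
#' @param assoc Association matrix (square symmetric or bipartite), with
#'   dimnames identifying the features.
#' @param cutoff Absolute association cutoff in (0, 1].
#' @param node_blocks Optional named vector mapping feature IDs to block
#'   labels.
#' @param drop_isolated Drop nodes without any surviving edge
#'   (default `TRUE`).
#' @param provenance Edge provenance label, e.g. `"pairwise-correlation"`
#'   or `"spls-similarity"`.
#' @return An `omics_network`: list with `nodes` (id, block) and `edges`
#'   (source, target, weight, sign, provenance) data frames.
#' @export
threshold_network <- function(assoc, cutoff, node_blocks = NULL,
                              drop_isolated = TRUE,
                              provenance = "pairwise-correlation") {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  assoc <- as.matrix(assoc)
  square <- nrow(assoc) == ncol(assoc) &&
    identical(rownames(assoc), colnames(assoc))
  if (square) {
    idx <- which(upper.tri(assoc) & !is.na(assoc) & abs(assoc) >= cutoff,
                 arr.ind = TRUE)
  } else {
    idx <- which(!is.na(assoc) & abs(assoc) >= cutoff, arr.ind = TRUE)
  }
  w <- assoc[idx]
  edges <- data.frame(
    source = rownames(assoc)[idx[, 1]],
    target = colnames(assoc)[idx[, 2]],
    weight = w,
    sign = ifelse(w >= 0, "+", "-"),
    provenance = rep_len(provenance, length(w)),
    stringsAsFactors = FALSE
  )
  ids <- if (square) rownames(assoc) else c(rownames(assoc), colnames(assoc))
  if (drop_isolated) ids <- intersect(ids, unique(c(edges$source, edges$target)))
  nodes <- data.frame(
    id = ids,
    block = if (is.null(node_blocks)) rep(NA_character_, length(ids)) else
      as.character(node_blocks[ids]),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff),
            class = "omics_network")
}

#' Merge two networks, keeping per-edge provenance
#'
#' @param a,b `omics_network` objects.
#' @return Combined `omics_network`; duplicate edges (same unordered pair
#'   and provenance) are kept once.
#' @export
merge_networks <- function(a, b) {
  nodes <- unique(rbind(a$nodes, b$nodes))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  edges <- rbind(a$edges, b$edges)
  key <- apply(edges, 1, function(e) {
    paste(sort(c(e[["source"]], e[["target"]])), e[["provenance"]],
          collapse = "|")
  })
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 cutoff = min(a$cutoff, b$cutoff)),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat("<omics_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (|association| >= ", x$cutoff, ")\n", sep = "")
  invisible(x)
}

#' Export a network as a SIF-style edge list (TSV)
#'
#' Columns: source, target, weight, sign, provenance (plus `directed` if
#' present, for Granger edge lists).
#'
#' @param net An `omics_network` or an edge data frame.
#' @param path Output file.
#' @export
write_sif <- function(net, path) {
  edges <- if (inherits(net, "omics_network")) net$edges else net
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML, with block labels as node attributes
#'
#' @param net An `omics_network`.
#' @param path Output file.
#' @export
write_graphml <- function(net, path) {
  vertices <- net$nodes
  vertices$block[is.na(vertices$block)] <- "unknown"
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = vertices)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
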