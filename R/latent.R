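#' Autoscale a samples-by-features matrix
#'
#' Centers every feature (column) to mean 0 and scales it to unit SD
#' (n - 1 denominator, so scores are reproducible bit for bit). Constant
#' features cannot be scaled and are dropped with a warning.
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @return Scaled matrix with attributes `center`, `scale` and `dropped`
#'   (names of constant features removed).
#' @export
autoscale <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[sdv == 0]
  if (length(dropped)) {
    warning("dropping constant feature(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    keep <- sdv > 0
    x <- x[, keep, drop = FALSE]
    ctr <- ctr[keep]
    sdv <- sdv[keep]
  }
  out <- sweep(sweep(x, 2, ctr, "-"), 2, sdv, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sdv
  attr(out, "dropped") <- dropped
  out
}

#' Invert [autoscale()]
#' @param x Matrix produced by [autoscale()] (its `center`/`scale`
#'   attributes are used).
#' @export
unscale <- function(x) {
  out <- sweep(sweep(x, 2, attr(x, "scale"), "*"), 2, attr(x, "center"), "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  attr(out, "dropped") <- NULL
  out
}

#' Fix component signs so the largest-magnitude loading is positive
#' @keywords internal
fix_signs <- function(weights, ...) {
  flips <- apply(weights, 2, function(w) {
    i <- which.max(abs(w))
    if (w[i] < 0) -1 else 1
  })
  mats <- list(weights, ...)
  lapply(mats, function(m) sweep(m, 2, flips, "*"))
}

#' Principal component analysis by singular value decomposition
#'
#' Scores are `U %*% D` of the SVD of the (already autoscaled) matrix;
#' explained variance per component is the squared singular value over the
#' total. Component signs follow a deterministic convention: the
#' largest-magnitude loading entry of each component is positive.
#'
#' @param x Autoscaled matrix (samples x features), e.g. from
#'   [autoscale()].
#' @param ncomp Number of components, at most `min(n - 1, p)`.
#' @return A `latent_model` with `scores` (n x ncomp), `loadings`
#'   (p x ncomp) and `explained_variance`.
#' @export
pca <- function(x, ncomp = 2) {
  x <- as.matrix(x)
  maxc <- min(nrow(x) - 1L, ncol(x))
  if (ncomp > maxc) {
    stop("parameter error: `ncomp` must be at most min(n - 1, p) = ", maxc,
         call. = FALSE)
  }
  sv <- svd(x)
  ev <- sv$d^2 / sum(sv$d^2)
  loadings <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- sv$u[, seq_len(ncomp), drop = FALSE] %*%
    diag(sv$d[seq_len(ncomp)], ncomp)
  fixed <- fix_signs(loadings, scores)
  loadings <- fixed[[1]]; scores <- fixed[[2]]
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
  structure(
    list(method = "pca", ncomp = ncomp, scores = scores, loadings = loadings,
         explained_variance = ev[seq_len(ncomp)]),
    class = "latent_model"
  )
}

#' Sparse partial least squares (regression mode)
#'
#' NIPALS-style alternating updates per component: the X-weight is the
#' (soft-selected, renormalized) image `t(X) %*% Y %*% v`, keeping only the
#' `keepX` largest-magnitude entries (ties broken by feature order); the
#' Y-weight is the normalized `t(Y) %*% X %*% u`. Iteration stops when the
#' X-weight changes by less than `tol` (max absolute difference) or after
#' `max_iter` iterations, in which case the component is flagged
#' non-convergent but kept. X-scores are `t = X u`; both X and Y are then
#' deflated on `t` (regression mode), which makes successive X-scores
#' orthogonal. With `keepX = p` this is plain PLS2 regression.
#'
#' @param x Autoscaled predictor matrix (n x p).
#' @param y Autoscaled response matrix (n x q).
#' @param ncomp Number of components.
#' @param keepX Number of predictor variables retained per component;
#'   either one integer recycled over components or a vector of length
#'   `ncomp`. Default: all (no sparsity).
#' @param tol Convergence tolerance on the X-weight update.
#' @param max_iter Iteration cap per component.
#' @return A `latent_model` with X-scores (`scores`), Y-scores
#'   (`y_scores`), X-weights (`weights`, unit norm, `keepX` nonzeros),
#'   Y-weights (`y_weights`), regression loadings (`x_loadings`,
#'   `y_loadings`), `keepX`, per-component `iterations`, `converged`
#'   flags and `explained_variance` (fraction of total X sum of squares
#'   captured by each score).
#' @export
spls <- function(x, y, ncomp = 2, keepX = ncol(x), tol = 1e-6,
                 max_iter = 500) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) {
    stop("`x` and `y` must have the same number of samples", call. = FALSE)
  }
  p <- ncol(x); q <- ncol(y)
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1 | keepX > p)) {
    stop("parameter error: `keepX` must lie in [1, ncol(x)]", call. = FALSE)
  }
  total_ss <- sum(x^2)
  Xh <- x; Yh <- y
  U <- matrix(0, p, ncomp); V <- matrix(0, q, ncomp)
  Tm <- matrix(0, nrow(x), ncomp); S <- matrix(0, nrow(x), ncomp)
  C <- matrix(0, p, ncomp); D <- matrix(0, q, ncomp)
  iters <- integer(ncomp); conv <- logical(ncomp); ev <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    m <- crossprod(Xh, Yh)
    sv <- svd(m, nu = 1, nv = 1)
    v <- sv$v[, 1]
    u <- soft_select(m %*% v, keepX[h])
    for (it in seq_len(max_iter)) {
      v_new <- crossprod(m, u)
      v_new <- v_new / vec_norm(v_new)
      u_new <- soft_select(m %*% v_new, keepX[h])
      delta <- max(abs(u_new - u))
      u <- u_new; v <- v_new
      if (delta < tol) break
    }
    iters[h] <- it
    conv[h] <- delta < tol
    if (!conv[h]) {
      warning("sPLS component ", h, " did not converge in ", max_iter,
              " iterations", call. = FALSE)
    }
    t_h <- drop(Xh %*% u)
    s_h <- drop(Yh %*% v)
    tt <- drop(crossprod(t_h))
    c_h <- drop(crossprod(Xh, t_h)) / tt
    d_h <- drop(crossprod(Yh, t_h)) / tt
    ## deterministic sign: largest-|u| entry positive
    i_max <- which.max(abs(u))
    if (u[i_max] < 0) {
      u <- -u; v <- -v; t_h <- -t_h; s_h <- -s_h; c_h <- -c_h; d_h <- -d_h
    }
    Xh <- Xh - tcrossprod(t_h, c_h)
    Yh <- Yh - tcrossprod(t_h, d_h)
    U[, h] <- u; V[, h] <- v; Tm[, h] <- t_h; S[, h] <- s_h
    C[, h] <- c_h; D[, h] <- d_h
    ev[h] <- sum(tcrossprod(t_h, c_h)^2) / total_ss
  }
  comp <- paste0("comp", seq_len(ncomp))
  dimnames(U) <- list(colnames(x), comp)
  dimnames(V) <- list(colnames(y), comp)
  dimnames(Tm) <- dimnames(S) <- list(rownames(x), comp)
  dimnames(C) <- list(colnames(x), comp)
  dimnames(D) <- list(colnames(y), comp)
  structure(
    list(method = "spls", ncomp = ncomp, keepX = keepX,
         scores = Tm, y_scores = S, weights = U, y_weights = V,
         x_loadings = C, y_loadings = D,
         iterations = iters, converged = conv, explained_variance = ev),
    class = "latent_model"
  )
}

#' @keywords internal
vec_norm <- function(v) sqrt(sum(v^2))

#' Keep the k largest-magnitude entries, zero the rest, renormalize
#' @keywords internal
soft_select <- function(w, k) {
  w <- drop(w)
  if (k < length(w)) {
    drop_idx <- order(-abs(w))[-seq_len(k)]  # ties broken by feature order
    w[drop_idx] <- 0
  }
  w / vec_norm(w)
}

#' PLS discriminant analysis
#'
#' PLS2 regression of the autoscaled one-hot class-membership matrix on
#' the predictors, via [spls()] with no sparsity: one numerical core, two
#' entry points.
#'
#' @param x Autoscaled predictor matrix (samples x features).
#' @param class_labels Factor (or coercible) of class labels, at least two
#'   classes.
#' @param ncomp Number of components.
#' @return A `latent_model` (method `"plsda"`) with the class labels
#'   attached as `labels`.
#' @export
plsda <- function(x, class_labels, ncomp = 2) {
  cl <- droplevels(as.factor(class_labels))
  if (nlevels(cl) < 2L) {
    stop("design error: PLS-DA needs at least two classes", call. = FALSE)
  }
  if (min(table(cl)) < 2L) {
    warning("class(es) with a single sample: low degrees of freedom",
            call. = FALSE)
  }
  y <- stats::model.matrix(~ cl - 1)
  colnames(y) <- levels(cl)
  y <- autoscale(y)
  model <- spls(x, y, ncomp = ncomp, keepX = ncol(x))
  model$method <- "plsda"
  model$labels <- cl
  model
}

#' @export
print.latent_model <- function(x, ...) {
  cat("<latent_model> method=", x$method, ", ncomp=", x$ncomp,
      ", explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write scores and loadings as TSV plus a JSON model summary
#'
#' @param model A `latent_model`.
#' @param dir Output directory.
#' @param prefix File-name prefix (defaults to the method).
#' @export
write_latent_model <- function(model, dir, prefix = model$method) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_tsv(model$scores, file.path(dir, paste0(prefix, "_scores.tsv")),
                    id_name = "sample_id")
  load_mat <- if (model$method == "pca") model$loadings else model$weights
  write_feature_tsv(load_mat, file.path(dir, paste0(prefix, "_loadings.tsv")))
  summary <- list(method = model$method, ncomp = model$ncomp,
                  keepX = model$keepX, iterations = model$iterations,
                  converged = model$converged,
                  explained_variance = model$explained_variance)
  jsonlite::write_json(summary[!vapply(summary, is.null, logical(1))],
                       file.path(dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
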