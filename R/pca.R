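#' Two-component PCA of samples
#'
#' Column-mean-centred principal component analysis of the samples of a
#' log2 expression matrix, as a 2-D picture of a multivariate expression
#' dataset. Components are unscaled (covariance PCA); signs are fixed
#' deterministically by making the largest-magnitude loading of each
#' component positive. Assays with masked cells are dropped before
#' decomposition with a warning.
#'
#' @param x An [rq_matrix()], `dct_matrix` or log2 matrix with >= 3
#'   samples, >= 2 assays and non-zero variance.
#' @param assays Optional assay subset (e.g. a `selection_result`'s
#'   `retained` set).
#' @return A list of class `pca_scores`: `scores` (samples x all
#'   components; the first two are the plotting plane),
#'   `explained_variance` (fraction per component, summing to 1),
#'   `loadings` (assays x components), `center` (per-assay means).
#' @export
pca_scores <- function(x, assays = NULL) {
  expr <- log2_expression(x)
  if (!is.null(assays)) {
    unknown <- setdiff(assays, rownames(expr))
    if (length(unknown))
      stop("unknown assay(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    expr <- expr[assays, , drop = FALSE]
  }
  complete <- rowSums(is.na(expr)) == 0
  if (!all(complete)) {
    warning(sum(!complete), " assay(s) with masked cells dropped before PCA",
            call. = FALSE)
    expr <- expr[complete, , drop = FALSE]
  }
  if (ncol(expr) < 3) stop("PCA needs >= 3 samples", call. = FALSE)
  if (nrow(expr) < 2) stop("PCA needs >= 2 assays", call. = FALSE)
  X <- t(expr)                               # samples x assays
  if (all(abs(sweep(X, 2, colMeans(X))) < 1e-12))
    stop("constant matrix: no principal directions", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  # deterministic signs: largest-|loading| assay positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x,
                 explained_variance = ev / sum(ev),
                 loadings = pc$rotation,
                 center = pc$center),
            class = "pca_scores")
}

#' @export
print.pca_scores <- function(x, ...) {
  cat(sprintf("pca_scores: %d samples, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' Mean silhouette width of labelled groups in PCA score space
#'
#' Summary of how well groups separate on the first two components:
#' per-sample silhouette widths computed from Euclidean distances in the
#' 2-D score plane, averaged.
#'
#' @param pca A [pca_scores()] result.
#' @param groups Group labels named by sample id.
#' @return Mean silhouette width (in `[-1, 1]`).
#' @export
score_silhouette <- function(pca, groups) {
  sc <- pca$scores[, 1:2, drop = FALSE]
  groups <- groups[rownames(sc)]
  d <- as.matrix(stats::dist(sc))
  widths <- vapply(seq_len(nrow(sc)), function(i) {
    own <- groups == groups[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(nrow(sc)) != i]) else 0
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g)
      mean(d[i, groups == g]), numeric(1)))
    if (sum(own) == 1) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(widths)
}
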