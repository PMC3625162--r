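# Feature-selection stages: control-line nonspecific filtering,
# supervised per-assay ANOVA, and PCA-loading selection. All operate on
# the log2 expression scale (one qPCR cycle = one log2 unit), where
# Gaussian Ct noise stays Gaussian.

#' Selection result container
#'
#' Shared return type of every selection stage: the retained assay ids,
#' the per-assay statistics that were evaluated, and a record of the
#' criteria that admitted each assay so the selection is auditable.
#'
#' @param retained Character vector of retained assay ids.
#' @param stats Data frame of per-assay statistics (one row per assay).
#' @param criteria Named list recording the rule and its parameters.
#' @param skipped Optional data frame of assays that could not be tested,
#'   with reasons.
#' @return An object of class `selection_result`.
#' @export
selection_result <- function(retained, stats, criteria, skipped = NULL) {
  structure(list(retained = as.character(retained), stats = stats,
                 criteria = criteria, skipped = skipped),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result (%s): %d of %d assays retained\n",
              x$criteria$method %||% "?", length(x$retained),
              nrow(x$stats) + NROW(x$skipped)))
  invisible(x)
}

.anova_by_assay <- function(expr, groups, var_equal = TRUE,
                            min_group_n = 1) {
  groups <- groups[colnames(expr)]
  p <- rep(NA_real_, nrow(expr))
  reason <- rep(NA_character_, nrow(expr))
  for (i in seq_len(nrow(expr))) {
    v <- expr[i, ]
    ok <- !is.na(v)
    tab <- table(groups[ok])
    usable <- sum(tab >= min_group_n)
    if (usable < 2) {
      reason[i] <- "fewer than 2 usable groups"
      next
    }
    p[i] <- .anova_p(v, groups, var_equal = var_equal)
    if (is.na(p[i])) reason[i] <- "no residual degrees of freedom"
  }
  list(p = stats::setNames(p, rownames(expr)), reason = reason)
}

#' Nonspecific filter from an empty-vector control line
#'
#' Assays that respond to the culture conditions in the empty-vector
#' control line (MIGR) cannot be attributed to the pathway of interest:
#' whatever moves them is not KIT. Each assay is tested by one-way ANOVA
#' of its log2 expression across conditions within the control line, and
#' assays with p below `alpha` are excluded. An assay with identical
#' control values everywhere carries no evidence of a condition effect
#' and is retained (p = 1 by convention).
#'
#' @param rq An [rq_matrix()] (or `dct_matrix`/log2 matrix) holding the
#'   control-line samples at least.
#' @param conditions Character vector of condition labels named by
#'   control-line sample id; each condition needs >= 2 replicates.
#' @param alpha Exclusion threshold on the ANOVA p-value (default 0.05).
#' @param var_equal Classic equal-variance ANOVA (default); `FALSE` for
#'   the Welch variant.
#' @return A [selection_result()]; `stats` has per-assay p-values,
#'   `retained` is exactly the set with `p >= alpha`.
#' @export
nonspecific_filter <- function(rq, conditions, alpha = 0.05,
                               var_equal = TRUE) {
  expr <- log2_expression(rq)
  if (is.null(names(conditions)))
    stop("`conditions` must be named by control sample id", call. = FALSE)
  ctrl <- intersect(colnames(expr), names(conditions))
  if (length(unique(conditions[ctrl])) < 2)
    stop("control line must span at least 2 conditions", call. = FALSE)
  tab <- table(conditions[ctrl])
  if (any(tab < 2))
    stop("condition(s) with fewer than 2 control replicates: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  expr <- expr[, ctrl, drop = FALSE]
  res <- .anova_by_assay(expr, conditions[ctrl], var_equal = var_equal)
  p <- res$p
  retained <- names(p)[!is.na(p) & p >= alpha]
  selection_result(
    retained = retained,
    stats = data.frame(assay = names(p), p.value = unname(p),
                       excluded = !is.na(p) & p < alpha, row.names = NULL),
    criteria = list(method = "nonspecific_filter", alpha = alpha,
                    var_equal = var_equal,
                    conditions = sort(unique(unname(conditions[ctrl])))),
    skipped = if (anyNA(p))
      data.frame(assay = names(p)[is.na(p)],
                 reason = res$reason[is.na(p)], row.names = NULL))
}

#' Supervised per-assay ANOVA selection
#'
#' One-way ANOVA of log2 expression across sample groups, assay by assay;
#' assays with p below `alpha` are retained as group-discriminating.
#' Assays for which fewer than two groups have present values are skipped
#' and reported in `skipped` rather than silently dropped.
#'
#' @param rq An [rq_matrix()], `dct_matrix` or log2 matrix.
#' @param groups Character vector of group labels named by sample id;
#'   samples not named are ignored.
#' @param alpha Retention threshold on the p-value (default 0.05).
#' @param var_equal Classic equal-variance ANOVA (default); `FALSE` for
#'   Welch.
#' @return A [selection_result()].
#' @export
supervised_anova_select <- function(rq, groups, alpha = 0.05,
                                    var_equal = TRUE) {
  expr <- log2_expression(rq)
  if (is.null(names(groups)))
    stop("`groups` must be named by sample id", call. = FALSE)
  use <- intersect(colnames(expr), names(groups))
  if (length(unique(groups[use])) < 2)
    stop("need at least 2 groups", call. = FALSE)
  expr <- expr[, use, drop = FALSE]
  res <- .anova_by_assay(expr, groups[use], var_equal = var_equal)
  p <- res$p
  retained <- names(p)[!is.na(p) & p < alpha]
  selection_result(
    retained = retained,
    stats = data.frame(assay = names(p), p.value = unname(p),
                       row.names = NULL),
    criteria = list(method = "supervised_anova", alpha = alpha,
                    var_equal = var_equal,
                    groups = sort(unique(unname(groups[use])))),
    skipped = if (anyNA(p))
      data.frame(assay = names(p)[is.na(p)],
                 reason = res$reason[is.na(p)], row.names = NULL))
}

#' PCA-loading gene selection
#'
#' Ranks genes by how much they drive the two leading principal
#' components of the column-mean-centred log2 expression matrix — the
#' norm of each gene's loadings on components 1 and 2, weighted by the
#' component standard deviations so that a degenerate component
#' contributes nothing — and
#' keeps the top `k`. This operationalizes "frequently deregulated across
#' groups" as "large contribution to the dominant variance directions";
#' it is a reconstruction of that idea, not a significance test. Genes
#' with masked cells are dropped (with a warning) before decomposition;
#' ties in the loading norm break lexicographically by gene id.
#'
#' @param rq An [rq_matrix()], `dct_matrix` or log2 matrix with >= 3
#'   samples.
#' @param k Number of genes to keep (at most the number of usable genes).
#' @return A [selection_result()] whose `stats` hold each gene's loading
#'   norm and per-component loadings, ranked.
#' @export
pca_gene_selection <- function(rq, k) {
  expr <- log2_expression(rq)
  complete <- rowSums(is.na(expr)) == 0
  if (!all(complete)) {
    warning(sum(!complete), " gene(s) with masked cells dropped before PCA",
            call. = FALSE)
    expr <- expr[complete, , drop = FALSE]
  }
  if (ncol(expr) < 3) stop("PCA selection needs >= 3 samples", call. = FALSE)
  if (k > nrow(expr))
    stop("k exceeds the number of usable genes", call. = FALSE)
  sc <- pca_scores(expr)
  keep_pc <- seq_len(min(2, ncol(sc$loadings)))
  load2 <- sc$loadings[, keep_pc, drop = FALSE]
  sdev <- sqrt(sc$explained_variance[keep_pc])   # relative component scale
  magnitude <- sqrt(rowSums(sweep(load2, 2, sdev, `*`)^2))
  ord <- order(-magnitude, rownames(load2))
  ranked <- data.frame(assay = rownames(load2)[ord],
                       loading_norm = magnitude[ord],
                       pc1 = load2[ord, 1],
                       pc2 = if (ncol(load2) > 1) load2[ord, 2] else NA_real_,
                       row.names = NULL)
  selection_result(
    retained = ranked$assay[seq_len(k)], stats = ranked,
    criteria = list(method = "pca_loading", k = k, components = 1:2))
}
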