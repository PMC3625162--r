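# Sample-classification surface: hierarchical clustering on log2
# expression with missingness-aware Euclidean distances, the supervised
# (ANOVA-gated) variant, and quantitative dendrogram topology checks that
# replace visual dendrogram reading.

#' Pairwise-complete rescaled Euclidean distance
#'
#' Distance between samples on the jointly present assays only, rescaled
#' by `sqrt(p / shared)` (p = number of assays used) so that distances
#' stay comparable across pairs with different non-detect loads; with no
#' missing cells this is exactly the plain Euclidean distance. A sample
#' pair sharing no assay has no defined distance and is an error.
#'
#' @param expr Log2 expression matrix, assays x samples.
#' @return A `dist` object over samples.
#' @export
rescaled_euclidean_dist <- function(expr) {
  n <- ncol(expr)
  p <- nrow(expr)
  obs <- !is.na(expr)
  d <- matrix(0, n, n, dimnames = list(colnames(expr), colnames(expr)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    shared <- obs[, i] & obs[, j]
    m <- sum(shared)
    if (m == 0)
      stop(sprintf("samples %s and %s share no present assay",
                   colnames(expr)[i], colnames(expr)[j]), call. = FALSE)
    diff <- expr[shared, i] - expr[shared, j]
    d[i, j] <- d[j, i] <- sqrt(sum(diff^2) * p / m)
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of samples
#'
#' Average-linkage (UPGMA) Euclidean clustering of samples on log2
#' expression, optionally restricted to a selected assay subset. Samples
#' are sorted lexicographically by id before clustering so the result is
#' invariant to input order; missing cells are handled by the
#' pairwise-complete rescaled distance (listwise deletion of incomplete
#' assays is available via `missing = "listwise"`).
#'
#' @param x An [rq_matrix()], `dct_matrix` or log2 matrix.
#' @param assays Optional character vector restricting the assays used.
#' @param linkage `"average"` (default), `"complete"`, `"single"` or
#'   `"ward.D2"`.
#' @param missing `"pairwise"` (default) or `"listwise"`.
#' @param standardize Z-score each assay across samples first (default
#'   `FALSE`: the heat is in relative expression already).
#' @return An `hclust` object with attributes `metric`, `linkage` and
#'   (for the supervised variant) `selection`.
#' @export
hierarchical_cluster <- function(x, assays = NULL,
                                 linkage = c("average", "complete",
                                             "single", "ward.D2"),
                                 missing = c("pairwise", "listwise"),
                                 standardize = FALSE) {
  linkage <- match.arg(linkage)
  missing <- match.arg(missing)
  expr <- log2_expression(x)
  if (!is.null(assays)) {
    unknown <- setdiff(assays, rownames(expr))
    if (length(unknown))
      stop("unknown assay(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    expr <- expr[assays, , drop = FALSE]
  }
  if (ncol(expr) < 2) stop("need at least 2 samples", call. = FALSE)
  expr <- expr[, order(colnames(expr)), drop = FALSE]
  if (missing == "listwise")
    expr <- expr[rowSums(is.na(expr)) == 0, , drop = FALSE]
  if (standardize) {
    sds <- apply(expr, 1, stats::sd, na.rm = TRUE)
    expr <- (expr - rowMeans(expr, na.rm = TRUE)) / ifelse(sds > 0, sds, 1)
  }
  d <- rescaled_euclidean_dist(expr)
  h <- stats::hclust(d, method = linkage)
  attr(h, "metric") <- "euclidean(pairwise-rescaled)"
  attr(h, "linkage") <- linkage
  h
}

#' Supervised hierarchical clustering
#'
#' Composition of [supervised_anova_select()] and
#' [hierarchical_cluster()]: samples are clustered on the assays whose
#' ANOVA p-value across `groups` falls below `alpha`. The selection
#' record is attached to the returned tree (`attr(, "selection")`).
#' With `alpha = 1` no assay is filtered and the result equals the
#' unsupervised tree.
#'
#' @inheritParams hierarchical_cluster
#' @param groups Group labels named by sample id (the supervision).
#' @param alpha ANOVA retention threshold.
#' @param ... Passed on to [hierarchical_cluster()].
#' @return An `hclust` with the `selection_result` attached.
#' @export
supervised_cluster <- function(x, groups, alpha = 0.05, ...) {
  sel <- supervised_anova_select(x, groups, alpha = alpha)
  if (!length(sel$retained))
    stop("supervised selection retained no assay; increase `alpha`",
         call. = FALSE)
  h <- hierarchical_cluster(x, assays = sel$retained, ...)
  attr(h, "selection") <- sel
  h
}

# leaf-id sets for every internal node of an hclust tree
.node_leaves <- function(h) {
  n <- length(h$order)
  leaves <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    pick <- lapply(h$merge[k, ], function(m)
      if (m < 0) h$labels[-m] else leaves[[m]])
    leaves[[k]] <- c(pick[[1]], pick[[2]])
  }
  leaves
}

#' Smallest enclosing subtree and monophyly
#'
#' `smallest_subtree()` returns the leaf set of the smallest subtree (an
#' internal node's clade, or a single leaf) containing all of `samples`.
#' `is_monophyletic()` tests whether some subtree contains exactly
#' `samples` — a single sample is trivially monophyletic.
#'
#' @param h An `hclust` tree with leaf labels.
#' @param samples Character vector of leaf ids.
#' @return `smallest_subtree()`: character vector of leaf ids;
#'   `is_monophyletic()`: logical.
#' @export
smallest_subtree <- function(h, samples) {
  unknown <- setdiff(samples, h$labels)
  if (length(unknown))
    stop("sample(s) not in the tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(samples) <= 1) return(samples)
  leaves <- .node_leaves(h)
  sizes <- lengths(leaves)
  enclosing <- which(vapply(leaves, function(l) all(samples %in% l),
                            logical(1)))
  leaves[[enclosing[which.min(sizes[enclosing])]]]
}

#' @rdname smallest_subtree
#' @export
is_monophyletic <- function(h, samples) {
  setequal(smallest_subtree(h, samples), samples)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 means identical
#' partitions, and a random labeling scores near 0.
#'
#' @param a,b Two labelings of the same elements (vectors, matched by
#'   position or by names if both are named).
#' @return Numeric scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Quantitative dendrogram topology report
#'
#' Replaces visual dendrogram reading with boolean checks: for each group
#' label, is the group monophyletic, and what is the leaf set of its
#' smallest enclosing subtree; for each pair of groups, are their
#' smallest enclosing subtrees disjoint; and the adjusted Rand index
#' between the group labels and the tree cut at `k` clusters.
#'
#' @param h An `hclust` tree.
#' @param groups Group labels named by sample id; every leaf must be
#'   annotated.
#' @param k Number of clusters at which to cut for the ARI (default: the
#'   number of distinct groups).
#' @return A list of class `topology_report`: `monophyly` (named
#'   logical), `subtrees` (named list), `disjoint` (named logical over
#'   group pairs), `ari`, `k`.
#' @export
topology_checks <- function(h, groups, k = NULL) {
  missing_s <- setdiff(h$labels, names(groups))
  if (length(missing_s))
    stop("unannotated leaf/leaves: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  groups <- groups[h$labels]
  labels <- sort(unique(groups))
  if (is.null(k)) k <- length(labels)
  subtrees <- lapply(labels, function(g)
    smallest_subtree(h, names(groups)[groups == g]))
  names(subtrees) <- labels
  mono <- vapply(labels, function(g)
    setequal(subtrees[[g]], names(groups)[groups == g]), logical(1))
  disjoint <- logical(0)
  if (length(labels) > 1) {
    pairs <- utils::combn(labels, 2)
    disjoint <- apply(pairs, 2, function(pr)
      length(intersect(subtrees[[pr[1]]], subtrees[[pr[2]]])) == 0)
    names(disjoint) <- apply(pairs, 2, paste, collapse = " vs ")
  }
  cut <- stats::cutree(h, k = k)
  structure(list(monophyly = mono, subtrees = subtrees,
                 disjoint = disjoint,
                 ari = adjusted_rand_index(groups, cut[names(groups)]),
                 k = k),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("topology report\n  monophyly:\n")
  for (g in names(x$monophyly))
    cat(sprintf("    %s: %s\n", g, x$monophyly[g]))
  cat(sprintf("  ARI at k = %d: %.3f\n", x$k, x$ari))
  invisible(x)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are merge-height differences (ultrametric tree).
#'
#' @param h An `hclust` tree.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `file`).
#' @export
as_newick <- function(h, file = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
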