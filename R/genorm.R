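#' geNorm-style reference-gene stability ranking
#'
#' For every candidate gene j, the stability value M(j) is the mean over
#' all partner genes k of the standard deviation across samples of the
#' log2 expression ratio of j vs k. A gene whose ratio to every other
#' candidate is constant across samples has M = 0; the lower M, the more
#' stable the gene as a normalizer. Optionally, the least stable gene is
#' excluded iteratively (recomputing M each round) down to a floor of two
#' genes, and the pairwise variation V(n) — the SD across samples of the
#' log2 ratio of the n-gene and (n+1)-gene geometric-mean normalization
#' factors — is recorded along the way.
#'
#' @param x Expression input: a [ct_matrix()], [dct_matrix()] or a plain
#'   log2-expression matrix (genes x samples); Ct-scale inputs are
#'   converted via [log2_expression()] (one cycle = one log2 unit).
#' @param genes Candidate gene ids (default: all rows). At least 3 genes
#'   and 3 samples are required and no masked cells are allowed among the
#'   candidates — impute or drop genes beforehand.
#' @param iterative If `TRUE` (default), perform stepwise exclusion.
#' @return A `genorm_ranking`: list with `ranking` (data frame `gene`,
#'   `M`, sorted ascending, ties broken by gene id), `exclusion_order`
#'   (most unstable first; `NULL` if not iterative) and
#'   `pairwise_variation` (data frame of V(n) or `NULL`).
#' @export
genorm_stability <- function(x, genes = NULL, iterative = TRUE) {
  expr <- log2_expression(x)
  if (is.null(genes)) genes <- rownames(expr)
  missing_g <- setdiff(genes, rownames(expr))
  if (length(missing_g))
    stop("candidate gene(s) not in the matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  expr <- expr[genes, , drop = FALSE]
  if (nrow(expr) < 3)
    stop("geNorm needs at least 3 candidate genes", call. = FALSE)
  if (ncol(expr) < 3)
    stop("geNorm needs at least 3 samples", call. = FALSE)
  if (anyNA(expr))
    stop("masked cells among candidate genes; impute or drop those genes ",
         "before the stability analysis", call. = FALSE)

  m_values <- function(e) {
    n <- nrow(e)
    m <- numeric(n)
    for (j in seq_len(n)) {
      sds <- vapply(seq_len(n)[-j],
                    function(k) stats::sd(e[j, ] - e[k, ]), numeric(1))
      m[j] <- mean(sds)
    }
    stats::setNames(m, rownames(e))
  }

  m_full <- m_values(expr)
  ord <- order(m_full, names(m_full))       # ascending M, ties by gene id
  ranking <- data.frame(gene = names(m_full)[ord], M = unname(m_full[ord]),
                        row.names = NULL)

  exclusion <- NULL
  pv <- NULL
  if (iterative) {
    e <- expr
    exclusion <- character(0)
    while (nrow(e) > 2) {
      m <- m_values(e)
      worst <- names(m)[order(-m, names(m))][1]
      exclusion <- c(exclusion, worst)
      e <- e[setdiff(rownames(e), worst), , drop = FALSE]
    }
    # stability order: the two survivors (by final M order) then the
    # excluded genes in reverse exclusion order
    stability_order <- c(rownames(e), rev(exclusion))
    # pairwise variation V(n/n+1) when genes are added in stability order
    nf <- function(gs) colMeans(expr[gs, , drop = FALSE])  # log2 geo-mean NF
    if (length(stability_order) > 2) {
      ns <- seq(2, length(stability_order) - 1)
      pv <- data.frame(
        n = ns,
        V = vapply(ns, function(n) {
          stats::sd(nf(stability_order[seq_len(n)]) -
                    nf(stability_order[seq_len(n + 1)]))
        }, numeric(1)))
    }
    exclusion <- list(order = exclusion, stability_order = stability_order)
  }

  structure(list(ranking = ranking, exclusion = exclusion,
                 pairwise_variation = pv),
            class = "genorm_ranking")
}

#' @export
print.genorm_ranking <- function(x, ...) {
  cat("geNorm stability ranking (ascending M):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
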