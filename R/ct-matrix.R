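#' Threshold-cycle (Ct) matrix
#'
#' The raw substrate of the pipeline: one threshold cycle per assay and
#' sample, with non-detects ("Undetermined" wells or wells discarded by a
#' Ct cut-off) carried as `NA` so that no numeric value leaks into
#' downstream statistics. Every sample belongs to exactly one card
#' (microfluidic plate), because global-median normalization is defined
#' per card.
#'
#' @param values Numeric matrix, assays in rows, samples in columns, with
#'   dimnames. `NA` marks a non-detect. Present values must be finite and
#'   within `[0, 50]` cycles.
#' @param card Character vector naming the card of every sample. Either
#'   named by sample id or in column order of `values`.
#' @param assay_class Optional character vector (`"mRNA"`, `"miRNA"` or
#'   `"control"`) per assay; defaults to `"mRNA"`.
#'
#' @return An object of class `ct_matrix`: a list with elements `values`,
#'   `card` (named by sample) and `assay_class` (named by assay).
#' @examples
#' m <- matrix(c(24, 31, NA, 28), nrow = 2,
#'             dimnames = list(c("Kit", "Mfap5"), c("S1", "S2")))
#' ct <- ct_matrix(m, card = c(S1 = "card1", S2 = "card1"))
#' n_detected(ct)
#' @export
ct_matrix <- function(values, card, assay_class = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (assays x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have assay rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate assay ids in `values`", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`", call. = FALSE)
  present <- values[!is.na(values)]
  if (length(present) && (!all(is.finite(present)) ||
                          any(present < 0) || any(present > 50)))
    stop("present Ct values must be finite and within [0, 50] cycles",
         call. = FALSE)

  card <- stats::setNames(as.character(card), names(card))
  if (is.null(names(card))) {
    if (length(card) != ncol(values))
      stop("unnamed `card` must have one entry per sample", call. = FALSE)
    names(card) <- colnames(values)
  }
  missing_card <- setdiff(colnames(values), names(card))
  if (length(missing_card))
    stop("samples with no card assignment: ",
         paste(missing_card, collapse = ", "), call. = FALSE)
  card <- card[colnames(values)]

  if (is.null(assay_class)) {
    assay_class <- stats::setNames(rep("mRNA", nrow(values)), rownames(values))
  } else {
    assay_class <- stats::setNames(as.character(assay_class),
                                   names(assay_class) %||% rownames(values))
    bad <- setdiff(assay_class, c("mRNA", "miRNA", "control"))
    if (length(bad))
      stop("assay_class must be 'mRNA', 'miRNA' or 'control'", call. = FALSE)
    missing_cls <- setdiff(rownames(values), names(assay_class))
    if (length(missing_cls))
      stop("assays with no class: ", paste(missing_cls, collapse = ", "),
           call. = FALSE)
    assay_class <- assay_class[rownames(values)]
  }

  structure(list(values = values, card = card, assay_class = assay_class),
            class = "ct_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples, %d cards, %d non-detects\n",
              nrow(x$values), ncol(x$values), length(unique(x$card)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

#' Detection mask and counts
#'
#' @param ct A [ct_matrix()].
#' @return `detect_mask()` returns a logical matrix (`TRUE` = detected);
#'   `n_detected()` the number of detected cells.
#' @export
detect_mask <- function(ct) !is.na(ct$values)

#' @rdname detect_mask
#' @export
n_detected <- function(ct) sum(!is.na(ct$values))

#' Relative-quantity (RQ) matrix
#'
#' Positive relative quantities per assay and sample, produced by
#' [delta_delta_ct()] or [ntarget_reference_gene()]. The reference
#' convention used to centre the data is recorded so downstream stages can
#' report it. Under `reference_mode = "virtual_housekeeping"` (mean-of-all
#' delta-delta-Ct), the per-assay geometric mean of present RQ is 1.
#'
#' @param rq Numeric matrix of positive relative quantities (`NA` = masked),
#'   with assay rownames and sample colnames.
#' @param reference_mode Character scalar describing the reference
#'   convention, e.g. `"virtual_housekeeping"`, `"reference_gene(ETV6)"` or
#'   `"baseline_sample(S1)"`.
#' @return An object of class `rq_matrix`.
#' @export
rq_matrix <- function(rq, reference_mode = "virtual_housekeeping") {
  if (!is.matrix(rq) || !is.numeric(rq))
    stop("`rq` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(rq)) || is.null(colnames(rq)))
    stop("`rq` must have assay rownames and sample colnames", call. = FALSE)
  present <- rq[!is.na(rq)]
  if (length(present) && (any(!is.finite(present)) || any(present <= 0)))
    stop("present relative quantities must be finite and > 0", call. = FALSE)
  structure(list(rq = rq, reference_mode = as.character(reference_mode)[1]),
            class = "rq_matrix")
}

#' @export
print.rq_matrix <- function(x, ...) {
  cat(sprintf("rq_matrix: %d assays x %d samples (reference: %s), %d masked\n",
              nrow(x$rq), ncol(x$rq), x$reference_mode, sum(is.na(x$rq))))
  invisible(x)
}

#' @export
dim.rq_matrix <- function(x) dim(x$rq)

#' Delta-Ct matrix
#'
#' Ct values normalized against a within-sample reference: either the
#' per-card global median (the "virtual housekeeping gene") or a named
#' reference assay. Produced by [delta_ct()].
#'
#' @param dct Numeric matrix of delta-Ct values (cycles; `NA` = masked).
#' @param centering Character scalar: `"card_median"` or
#'   `"reference_gene(<id>)"`.
#' @param card Named character vector, card per sample (kept so the
#'   per-card zero-median invariant remains checkable).
#' @return An object of class `dct_matrix`.
#' @export
dct_matrix <- function(dct, centering, card = NULL) {
  if (!is.matrix(dct) || !is.numeric(dct))
    stop("`dct` must be a numeric matrix", call. = FALSE)
  structure(list(dct = dct, centering = as.character(centering)[1],
                 card = card),
            class = "dct_matrix")
}

#' @export
print.dct_matrix <- function(x, ...) {
  cat(sprintf("dct_matrix: %d assays x %d samples (centering: %s)\n",
              nrow(x$dct), ncol(x$dct), x$centering))
  invisible(x)
}

#' Extract the log2-expression matrix from pipeline containers
#'
#' qPCR group statistics in this package are computed on the log2
#' expression scale, where Gaussian Ct noise stays Gaussian. For an
#' [rq_matrix()] this is `log2(rq)`; for a [dct_matrix()] it is `-dct`
#' (one cycle = one log2 unit); a plain matrix is returned unchanged.
#'
#' @param x An `rq_matrix`, `dct_matrix` or numeric matrix.
#' @return Numeric matrix, assays in rows, samples in columns.
#' @export
log2_expression <- function(x) {
  if (inherits(x, "rq_matrix")) return(log2(x$rq))
  if (inherits(x, "dct_matrix")) return(-x$dct)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("cannot extract a log2 expression matrix from class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' Sample annotation table
#'
#' Validates a per-sample annotation data frame against the pipeline's
#' closed vocabularies. Cell-line panels carry `genotype` (MIGR empty-vector
#' control, WT, hemizygous D6/D54, heterozygous WT/D6, WT/D54) and
#' `condition` (SCF+, SCF-, imatinib); tumour cohorts carry `mutation_class`
#' and `zygosity`. Extra clinical columns pass through untouched.
#'
#' @param ann Data frame with a `sample` column plus any of `genotype`,
#'   `condition`, `mutation_class`, `zygosity`, `replicate`.
#' @param samples Optional character vector of sample ids that must match
#'   the annotation exactly (e.g. `colnames` of a Ct matrix).
#' @return The validated data frame, classed `sample_annotation`.
#' @export
sample_annotation <- function(ann, samples = NULL) {
  ann <- as.data.frame(ann)
  if (!"sample" %in% names(ann))
    stop("annotation needs a `sample` column", call. = FALSE)
  ann$sample <- as.character(ann$sample)
  if (anyDuplicated(ann$sample))
    stop("duplicate sample ids in annotation", call. = FALSE)
  vocab <- list(
    genotype = c("MIGR", "WT", "D6", "D54", "WT/D6", "WT/D54"),
    condition = c("SCF+", "SCF-", "imatinib"),
    mutation_class = c("WT", "KIT_ex9", "KIT_ex11", "PDGFRA_ex18",
                       "PDGFRA_ex10_poly"),
    zygosity = c("heterozygous", "homozygous", "unknown"))
  for (col in intersect(names(vocab), names(ann))) {
    bad <- setdiff(stats::na.omit(unique(as.character(ann[[col]]))), vocab[[col]])
    if (length(bad))
      stop(sprintf("invalid %s label(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  if ("replicate" %in% names(ann) &&
      any(stats::na.omit(ann$replicate) < 1))
    stop("replicate index must be >= 1", call. = FALSE)
  if (!is.null(samples)) {
    if (!setequal(ann$sample, samples))
      stop("annotation sample ids do not match the expression matrix",
           call. = FALSE)
    ann <- ann[match(samples, ann$sample), , drop = FALSE]
    rownames(ann) <- NULL
  }
  class(ann) <- c("sample_annotation", "data.frame")
  ann
}

#' Named group vector from an annotation table
#'
#' @param ann A [sample_annotation()] (or plain data frame with a `sample`
#'   column).
#' @param columns Annotation columns to paste into the group label (e.g.
#'   `"genotype"`, or `c("genotype", "condition")`).
#' @param sep Separator between pasted columns.
#' @return Character vector of group labels named by sample id.
#' @export
annotation_groups <- function(ann, columns, sep = "|") {
  missing_cols <- setdiff(columns, names(ann))
  if (length(missing_cols))
    stop("annotation lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  labels <- do.call(paste, c(lapply(columns, function(col)
    as.character(ann[[col]])), sep = sep))
  stats::setNames(labels, ann$sample)
}
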