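# Quantification stack for low-density qPCR cards: Ct cut-off, per-card
# global-median correction (the "virtual housekeeping gene"), delta-Ct,
# delta-delta-Ct relative quantities, reference-gene Ntarget, per-tumour
# correcting factors and baseline-group fold differences.
#
# Sign conventions are fixed throughout so that higher expression implies
# a larger relative quantity: RQ = 2^(-ddCt), Ntarget = 2^(Ct_ref - Ct_target).

#' Discard late Ct values
#'
#' Wells with Ct above the cut-off are turned into non-detects; everything
#' else is untouched. Late threshold cycles sit near the stochastic limit
#' of single-template amplification and are unreliable as quantities; the
#' conventional cut-offs are 35 cycles for cell-line cards and 37 for
#' FFPE tumour material.
#'
#' @param ct A [ct_matrix()].
#' @param cutoff Cut-off in cycles, in `(0, 50]`.
#' @return A new `ct_matrix` (the input is not modified).
#' @export
apply_ct_cutoff <- function(ct, cutoff = 35) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff > 50)
    stop("`cutoff` must be a single value in (0, 50]", call. = FALSE)
  values <- ct$values
  values[!is.na(values) & values > cutoff] <- NA_real_
  ct_matrix(values, card = ct$card, assay_class = ct$assay_class)
}

.card_medians <- function(values, card) {
  cards <- unique(card)
  med <- vapply(cards, function(cd) {
    v <- values[, card == cd, drop = FALSE]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    stats::median(v)
  }, numeric(1))
  stats::setNames(med, cards)
}

#' Per-card global-median correction
#'
#' Aligns every card's median of present Ct values onto a common target,
#' by subtracting `median(card) - target` from all wells of the card. The
#' shared post-correction median behaves as a perfect "virtual
#' housekeeping gene": it is exactly stable across samples by
#' construction, which is what a biological reference gene only
#' approximates.
#'
#' @param ct A [ct_matrix()].
#' @param target `"median_of_medians"` (default: the median of the
#'   per-card medians, robust to cards with different non-detect loads) or
#'   an explicit Ct value in cycles.
#' @return A list with `ct` (corrected `ct_matrix`), `target` (the target
#'   median actually used) and `factors` (data frame of per-card medians
#'   and additive corrections, class `correction_factors`).
#' @export
card_median_correction <- function(ct, target = "median_of_medians") {
  stopifnot(inherits(ct, "ct_matrix"))
  med <- .card_medians(ct$values, ct$card)
  if (anyNA(med))
    stop("card(s) with no detected Ct value: ",
         paste(names(med)[is.na(med)], collapse = ", "), call. = FALSE)
  if (identical(target, "median_of_medians")) {
    target_value <- stats::median(med)
  } else if (is.numeric(target) && length(target) == 1 && is.finite(target)) {
    target_value <- target
  } else {
    stop("`target` must be \"median_of_medians\" or a single Ct value",
         call. = FALSE)
  }
  shift <- med - target_value                  # per card, in cycles
  values <- ct$values - rep(shift[ct$card], each = nrow(ct$values))
  factors <- data.frame(card = names(med), median = unname(med),
                        correction = -unname(shift))
  class(factors) <- c("correction_factors", "data.frame")
  list(ct = ct_matrix(values, card = ct$card, assay_class = ct$assay_class),
       target = target_value, factors = factors)
}

#' Delta-Ct against the card median or a reference gene
#'
#' In `"card_median"` mode each well is centred on its own card's median
#' of present Ct values (equivalently: run [card_median_correction()]
#' first and subtract the shared target median — the two routes commute).
#' In reference-gene mode, `dCt = Ct(assay) - Ct(reference)` per sample;
#' samples where the reference is a non-detect are fully masked with a
#' warning, never imputed.
#'
#' @param ct A [ct_matrix()].
#' @param centering `"card_median"` or the id of a reference assay.
#' @return A [dct_matrix()].
#' @export
delta_ct <- function(ct, centering = "card_median") {
  stopifnot(inherits(ct, "ct_matrix"))
  if (identical(centering, "card_median")) {
    med <- .card_medians(ct$values, ct$card)
    if (anyNA(med))
      stop("card(s) with no detected Ct value: ",
           paste(names(med)[is.na(med)], collapse = ", "), call. = FALSE)
    dct <- ct$values - rep(med[ct$card], each = nrow(ct$values))
    return(dct_matrix(dct, centering = "card_median", card = ct$card))
  }
  if (!centering %in% rownames(ct$values))
    stop("reference assay not in the matrix: ", centering, call. = FALSE)
  ref <- ct$values[centering, ]
  if (anyNA(ref)) {
    warning("reference gene ", centering, " undetected in sample(s): ",
            paste(colnames(ct$values)[is.na(ref)], collapse = ", "),
            "; those samples are masked", call. = FALSE)
  }
  dct <- sweep(ct$values, 2, ref, `-`)
  dct[, is.na(ref)] <- NA_real_
  dct_matrix(dct, centering = sprintf("reference_gene(%s)", centering),
             card = ct$card)
}

#' Delta-delta-Ct relative quantities
#'
#' Centres each assay's delta-Ct on a reference and converts to the linear
#' scale: `RQ = 2^-(dCt - ref)`. With `reference = "mean_of_all_samples"`
#' the per-assay arithmetic mean of present delta-Ct is used instead of a
#' designated calibrator sample; this makes the per-assay geometric mean
#' of RQ exactly 1 and avoids hanging every quantity off one (noisy)
#' sample. Assays with no present value are dropped with a warning.
#'
#' @param dct A [dct_matrix()].
#' @param reference `"mean_of_all_samples"` or a sample id (that sample
#'   then has RQ = 1 for every assay in which it is detected).
#' @return An [rq_matrix()].
#' @export
delta_delta_ct <- function(dct, reference = "mean_of_all_samples") {
  stopifnot(inherits(dct, "dct_matrix"))
  d <- dct$dct
  all_masked <- rowSums(!is.na(d)) == 0
  if (any(all_masked)) {
    warning("dropping assay(s) with no present value: ",
            paste(rownames(d)[all_masked], collapse = ", "), call. = FALSE)
    d <- d[!all_masked, , drop = FALSE]
  }
  if (identical(reference, "mean_of_all_samples")) {
    ref <- rowMeans(d, na.rm = TRUE)
    mode <- "virtual_housekeeping"
  } else {
    if (!reference %in% colnames(d))
      stop("reference sample not in the matrix: ", reference, call. = FALSE)
    ref <- d[, reference]
    if (anyNA(ref))
      warning("reference sample undetected for assay(s): ",
              paste(rownames(d)[is.na(ref)], collapse = ", "), call. = FALSE)
    mode <- sprintf("baseline_sample(%s)", reference)
  }
  rq <- 2^(-(d - ref))
  rq_matrix(rq, reference_mode = mode)
}

#' Ntarget relative quantity against a reference gene
#'
#' Classic single-reference-gene quantification:
#' `Ntarget = 2^(Ct_reference - Ct_target)` per sample, so a target
#' amplifying earlier (lower Ct) than the reference gets Ntarget > 1.
#' Cells where either assay is a non-detect are masked.
#'
#' @param ct A [ct_matrix()].
#' @param target_assay Assay id(s) to quantify; defaults to all assays
#'   except the reference.
#' @param reference_assay Id of the normalization gene (e.g. ETV6).
#' @return An [rq_matrix()] over the target assays.
#' @export
ntarget_reference_gene <- function(ct, target_assay = NULL, reference_assay) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!reference_assay %in% rownames(ct$values))
    stop("reference assay not in the matrix: ", reference_assay,
         call. = FALSE)
  if (is.null(target_assay))
    target_assay <- setdiff(rownames(ct$values), reference_assay)
  missing_t <- setdiff(target_assay, rownames(ct$values))
  if (length(missing_t))
    stop("target assay(s) not in the matrix: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  ref <- ct$values[reference_assay, ]
  tgt <- ct$values[target_assay, , drop = FALSE]
  rq <- 2^sweep(-tgt, 2, ref, `+`)      # 2^(Ct_ref - Ct_target)
  rq_matrix(rq, reference_mode = sprintf("reference_gene(%s)",
                                         reference_assay))
}

#' Tumour-specific correcting factors from a reference gene
#'
#' Computes, for each tumour j, `F_j = mean(Ct_ref) - Ct_ref(j)` (grand
#' mean over all tumours) and adds `F_j` to every assay of that tumour.
#' After correction the reference gene's Ct equals the grand mean in every
#' tumour, i.e. the reference is made perfectly stable and all other
#' assays are shifted with it. Additive on the Ct scale = multiplicative
#' on the linear scale.
#'
#' @param ct A [ct_matrix()] (samples = tumours).
#' @param reference_assay Id of the reference gene; it must be detected in
#'   every tumour, otherwise the normalizer is unusable and this is an
#'   error naming the offending tumours.
#' @return A list with `ct` (corrected matrix), `grand_mean` (cycles) and
#'   `factors` (per-tumour data frame, class `correction_factors`).
#' @export
tumor_correcting_factors <- function(ct, reference_assay) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!reference_assay %in% rownames(ct$values))
    stop("reference assay not in the matrix: ", reference_assay,
         call. = FALSE)
  ref <- ct$values[reference_assay, ]
  if (anyNA(ref))
    stop("reference assay ", reference_assay,
         " undetected in tumour(s): ",
         paste(colnames(ct$values)[is.na(ref)], collapse = ", "),
         call. = FALSE)
  grand_mean <- mean(ref)
  f <- grand_mean - ref
  values <- sweep(ct$values, 2, f, `+`)
  factors <- data.frame(sample = colnames(ct$values), reference_ct = unname(ref),
                        F = unname(f))
  class(factors) <- c("correction_factors", "data.frame")
  list(ct = ct_matrix(values, card = ct$card, assay_class = ct$assay_class),
       grand_mean = grand_mean, reference_assay = reference_assay,
       factors = factors)
}

.geo_mean <- function(x) exp(mean(log(x)))

#' Fold differences relative to a baseline group
#'
#' Expresses each sample's relative quantity as an N-fold difference
#' against the baseline group's average for that assay (e.g. mutant
#' tumours relative to WT tumours). Folds are ratios, so the baseline
#' average is geometric by default; the arithmetic mean is available for
#' sensitivity checks. Assays with no present baseline value are masked.
#'
#' @param rq An [rq_matrix()].
#' @param groups Character vector of group labels named by sample id (see
#'   [annotation_groups()]).
#' @param baseline_group Label of the baseline group.
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return An `rq_matrix` of fold differences,
#'   `reference_mode = "baseline_group(<label>)"`.
#' @export
fold_vs_baseline_group <- function(rq, groups, baseline_group,
                                   average = c("geometric", "arithmetic")) {
  stopifnot(inherits(rq, "rq_matrix"))
  average <- match.arg(average)
  groups <- groups[colnames(rq$rq)]
  if (anyNA(groups) || is.null(names(groups)))
    stop("`groups` must cover every sample of `rq` by name", call. = FALSE)
  base_samples <- names(groups)[groups == baseline_group]
  if (!length(base_samples))
    stop("no sample in baseline group: ", baseline_group, call. = FALSE)
  base <- apply(rq$rq[, base_samples, drop = FALSE], 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    if (average == "geometric") .geo_mean(v) else mean(v)
  })
  if (anyNA(base))
    warning("assay(s) with empty baseline masked: ",
            paste(rownames(rq$rq)[is.na(base)], collapse = ", "),
            call. = FALSE)
  fold <- rq$rq / base
  rq_matrix(fold,
            reference_mode = sprintf("baseline_group(%s)", baseline_group))
}
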