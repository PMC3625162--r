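# High-density expression-array stage: per-array median normalization,
# negative-control detection thresholds with present/marginal/absent
# calls, and the pairwise fold-change rule used to nominate candidate
# genes for the low-density qPCR cards.

#' Probe-intensity container
#'
#' @param raw Non-negative numeric matrix of raw intensities, probes in
#'   rows, arrays in columns, with dimnames.
#' @param probe_class Character vector per probe: `"target"` or
#'   `"negative_control"`.
#' @return An object of class `intensity_array` with elements `raw`,
#'   `probe_class`, and (after [median_normalize_array()] /
#'   [detection_threshold()]) `normalized`, `threshold`, `calls`.
#' @export
intensity_array <- function(raw, probe_class = NULL) {
  if (!is.matrix(raw) || !is.numeric(raw))
    stop("`raw` must be a numeric matrix (probes x arrays)", call. = FALSE)
  if (is.null(rownames(raw)) || is.null(colnames(raw)))
    stop("`raw` must have probe rownames and array colnames", call. = FALSE)
  if (any(!is.finite(raw)) || any(raw < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  if (is.null(probe_class))
    probe_class <- stats::setNames(rep("target", nrow(raw)), rownames(raw))
  probe_class <- stats::setNames(as.character(probe_class),
                                 names(probe_class) %||% rownames(raw))
  bad <- setdiff(probe_class, c("target", "negative_control"))
  if (length(bad))
    stop("probe_class must be 'target' or 'negative_control'", call. = FALSE)
  probe_class <- probe_class[rownames(raw)]
  structure(list(raw = raw, probe_class = probe_class,
                 normalized = NULL, threshold = NULL, calls = NULL),
            class = "intensity_array")
}

#' @export
print.intensity_array <- function(x, ...) {
  cat(sprintf(
    "intensity_array: %d probes (%d negative controls) x %d arrays%s\n",
    nrow(x$raw), sum(x$probe_class == "negative_control"), ncol(x$raw),
    if (is.null(x$normalized)) " [raw]" else " [normalized]"))
  invisible(x)
}

#' Median-normalize each array
#'
#' Divides every array by its own median intensity over all probes, so
#' that each array's median normalized intensity is exactly 1 and arrays
#' hybridized or scanned at different overall levels become comparable.
#'
#' @param ia An [intensity_array()].
#' @return The `intensity_array` with `normalized` filled in.
#' @export
median_normalize_array <- function(ia) {
  stopifnot(inherits(ia, "intensity_array"))
  med <- apply(ia$raw, 2, stats::median)
  if (any(med <= 0))
    stop("degenerate array(s) with non-positive median intensity: ",
         paste(colnames(ia$raw)[med <= 0], collapse = ", "), call. = FALSE)
  ia$normalized <- sweep(ia$raw, 2, med, `/`)
  ia
}

#' Detection threshold and present/marginal/absent calls
#'
#' Each array's detection threshold is `mean + k * SD` of the normalized
#' intensities of that array's negative-control probes. Probes below the
#' threshold are called `"absent"`, probes in `[threshold,
#' marginal_factor * threshold)` `"marginal"`, and probes at or above
#' `marginal_factor * threshold` `"present"` (a probe exactly at the
#' threshold is therefore not absent).
#'
#' @param ia A normalized [intensity_array()] (run
#'   [median_normalize_array()] first).
#' @param k Multiplier on the negative-control SD (default 3).
#' @param marginal_factor Upper edge of the marginal band as a multiple of
#'   the threshold (default 1.2).
#' @return The `intensity_array` with per-array `threshold` and a `calls`
#'   character matrix filled in.
#' @export
detection_threshold <- function(ia, k = 3, marginal_factor = 1.2) {
  stopifnot(inherits(ia, "intensity_array"))
  if (is.null(ia$normalized))
    stop("run median_normalize_array() before calling detection_threshold()",
         call. = FALSE)
  neg <- ia$probe_class == "negative_control"
  if (sum(neg) < 2)
    stop("need at least 2 negative-control probes", call. = FALSE)
  thr <- apply(ia$normalized[neg, , drop = FALSE], 2,
               function(v) mean(v) + k * stats::sd(v))
  calls <- matrix("present", nrow(ia$normalized), ncol(ia$normalized),
                  dimnames = dimnames(ia$normalized))
  for (j in seq_along(thr)) {
    v <- ia$normalized[, j]
    calls[v < thr[j], j] <- "absent"
    calls[v >= thr[j] & v < marginal_factor * thr[j], j] <- "marginal"
  }
  ia$threshold <- thr
  ia$calls <- calls
  ia
}

#' Pairwise fold-change gene selection between two groups
#'
#' Re-implements the candidate-gene rule used on median-normalized,
#' detection-called arrays. A target gene is retained iff
#' \enumerate{
#'   \item the average over all cross-group sample pairs of
#'     `max(a/b, b/a)` is at least `fc_threshold` (symmetric in group
#'     order),
#'   \item its normalized intensity exceeds `amplitude` in at least one of
#'     the compared samples, and
#'   \item it is called present or marginal in all samples of at least one
#'     of the two groups (`call_rule = "one_group"`, the default: the gene
#'     must be above background somewhere; `"all_samples"` demands it in
#'     both groups).
#' }
#' Zero intensities are floored at `floor` before forming ratios (and the
#' gene flagged), so a fold change is always finite.
#'
#' @param ia A normalized, called [intensity_array()].
#' @param group_a,group_b Character vectors of array/sample ids.
#' @param fc_threshold Minimum average pairwise fold change (default 2).
#' @param amplitude Minimum normalized intensity to be reached in at least
#'   one sample (default 1.3).
#' @param floor Positivity floor for ratios (default 0.01).
#' @param call_rule `"one_group"` or `"all_samples"`.
#' @return A [selection_result()] whose `stats` carry per-gene average
#'   fold change, maximum amplitude, call pass/fail and the floor flag.
#' @export
select_differential_genes <- function(ia, group_a, group_b,
                                      fc_threshold = 2, amplitude = 1.3,
                                      floor = 0.01,
                                      call_rule = c("one_group",
                                                    "all_samples")) {
  stopifnot(inherits(ia, "intensity_array"))
  call_rule <- match.arg(call_rule)
  if (is.null(ia$normalized) || is.null(ia$calls))
    stop("normalize and call the arrays first (median_normalize_array, ",
         "detection_threshold)", call. = FALSE)
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  unknown <- setdiff(c(group_a, group_b), colnames(ia$normalized))
  if (length(unknown))
    stop("unknown array id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  targets <- rownames(ia$normalized)[ia$probe_class == "target"]
  a <- ia$normalized[targets, group_a, drop = FALSE]
  b <- ia$normalized[targets, group_b, drop = FALSE]
  floored <- rowSums(a < floor) + rowSums(b < floor) > 0
  a <- pmax(a, floor)
  b <- pmax(b, floor)

  # average over all cross-group pairs of max(a/b, b/a)
  n_pairs <- ncol(a) * ncol(b)
  fc_sum <- matrix(0, length(targets), 1)
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    r <- a[, i] / b[, j]
    fc_sum <- fc_sum + pmax(r, 1 / r)
  }
  avg_fc <- as.vector(fc_sum) / n_pairs

  amp_ok <- apply(cbind(a, b), 1, max) > amplitude
  calls_a <- ia$calls[targets, group_a, drop = FALSE]
  calls_b <- ia$calls[targets, group_b, drop = FALSE]
  ok_a <- rowSums(calls_a == "absent") == 0
  ok_b <- rowSums(calls_b == "absent") == 0
  call_ok <- if (call_rule == "one_group") ok_a | ok_b else ok_a & ok_b

  retained <- avg_fc >= fc_threshold & amp_ok & call_ok
  stats_df <- data.frame(assay = targets, avg_fold_change = avg_fc,
                         max_amplitude = apply(cbind(a, b), 1, max),
                         call_ok = call_ok, amplitude_ok = amp_ok,
                         floored = floored, retained = retained,
                         row.names = NULL)
  selection_result(
    retained = targets[retained], stats = stats_df,
    criteria = list(method = "pairwise_fold_change",
                    fc_threshold = fc_threshold, amplitude = amplitude,
                    call_rule = call_rule, floor = floor,
                    n_a = length(group_a), n_b = length(group_b)))
}

#' Intersect a candidate list with the assays available on a card
#'
#' The high-density stage nominates more genes than a low-density card can
#' carry; the step down is a plain id intersection, preserving the
#' candidate order.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param available Character vector of assays available on the card.
#' @return Character vector of candidates that are available.
#' @export
intersect_available_assays <- function(candidates, available) {
  candidates[candidates %in% available]
}
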