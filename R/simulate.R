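# Synthetic Ct-data generators emulating the two study designs the
# pipeline was built for: a 6-line NIH3T3 panel expressing KIT-mutation
# genotypes under three culture conditions, profiled on a 94-assay mRNA
# card, and a 19-tumour GIST cohort (6 homozygous vs 13 heterozygous KIT
# exon-11 mutants) profiled on a 384-assay miRNA card. Plus a log-normal
# high-density array generator for the candidate-gene stage.
#
# The generative model is deliberately simple and fully declared:
#   Ct = baseline(assay) - effect(assay, group[, condition])
#        + card_offset(card) + batch(replicate, assay) + N(0, noise_sd)
# with non-detects arising mechanistically whenever Ct exceeds the
# instrument limit. Ground truth (which assays carry which effects) is
# returned alongside, so every downstream stage can be scored.

#' Cell-line panel design
#'
#' Default design ("paper-like" preset): 94 mRNA assays; genotypes MIGR
#' (empty vector), WT, D6, D54 (hemizygous) and WT/D6, WT/D54
#' (heterozygous) under conditions SCF+, SCF- and imatinib; replicates
#' 3/3/3/3/2/2 per condition, where replicate r of every line belongs to
#' the same experimental batch. A shared mutation signature
#' (`n_shared` assays, effect `hemi_effect` cycles, random signs) marks
#' all KIT-mutant lines, at full size in hemizygous lines and scaled by
#' `het_ratio` in heterozygous ones; D6 and D54 additionally differ on
#' disjoint `n_d6`/`n_d54` assay sets. `n_condition` assays respond to
#' the culture condition in every line including MIGR — the nonspecific
#' targets of the control-line filter.
#'
#' @param n_assays Number of assays on the card.
#' @param n_shared,n_d6,n_d54,n_condition Sizes of the planted assay sets.
#' @param hemi_effect Hemizygous signature effect in cycles.
#' @param het_ratio Heterozygous effect as a fraction of `hemi_effect`.
#' @param condition_effect Nonspecific condition effect in cycles.
#' @param replicates Named integer vector of replicates per line and
#'   condition.
#' @param noise_sd Well-level Gaussian noise SD (cycles).
#' @param batch_sd SD of the per-(replicate, assay) batch term shared by
#'   all lines of a replicate (cycles).
#' @param card_offset_sd SD of per-card additive offsets (cycles).
#' @param samples_per_card Samples loaded per microfluidic card.
#' @param baseline_range Range of per-assay baseline Ct (cycles).
#' @param detect_limit Instrument limit: simulated Ct beyond it becomes a
#'   non-detect.
#' @param noise_df Degrees of freedom of the well-level noise: `Inf`
#'   (default) for Gaussian, a finite value for variance-matched
#'   Student-t heavy tails (robustness checks).
#' @param dropout_rate Probability of an independent random non-detect
#'   per well, on top of the mechanistic instrument-limit censoring
#'   (default 0).
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A list of class `synthetic_design`.
#' @export
design_cell_line_panel <- function(n_assays = 94, n_shared = 20, n_d6 = 8,
                                   n_d54 = 8, n_condition = 15,
                                   hemi_effect = 1.5, het_ratio = 0.15,
                                   condition_effect = 1.0,
                                   replicates = c("MIGR" = 3, "WT" = 3,
                                                  "D6" = 3, "D54" = 3,
                                                  "WT/D6" = 2, "WT/D54" = 2),
                                   noise_sd = 0.3, batch_sd = 0.3,
                                   card_offset_sd = 0.5,
                                   samples_per_card = 4,
                                   baseline_range = c(22, 34),
                                   detect_limit = 40, noise_df = Inf,
                                   dropout_rate = 0, seed = 1L) {
  stopifnot(noise_sd >= 0, batch_sd >= 0, card_offset_sd >= 0,
            n_shared + n_d6 + n_d54 + n_condition <= n_assays,
            all(replicates >= 1), noise_df > 2,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(kind = "cell_line_panel", n_assays = n_assays,
                 n_shared = n_shared, n_d6 = n_d6, n_d54 = n_d54,
                 n_condition = n_condition, hemi_effect = hemi_effect,
                 het_ratio = het_ratio, condition_effect = condition_effect,
                 replicates = replicates, noise_sd = noise_sd,
                 batch_sd = batch_sd, card_offset_sd = card_offset_sd,
                 samples_per_card = samples_per_card,
                 baseline_range = baseline_range,
                 detect_limit = detect_limit, noise_df = noise_df,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "synthetic_design")
}

# well-level noise: Gaussian, or variance-matched Student-t for
# heavy-tailed robustness checks
.well_noise <- function(n, sd, df = Inf) {
  if (is.infinite(df)) return(stats::rnorm(n, 0, sd))
  stats::rt(n, df) * sd * sqrt((df - 2) / df)
}

.apply_dropout <- function(values, rate) {
  if (rate <= 0) return(values)
  values[stats::runif(length(values)) < rate] <- NA_real_
  values
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf("synthetic_design (%s), %d assays, seed %d\n",
              x$kind, x$n_assays, x$seed))
  invisible(x)
}

.assay_ids <- function(n, prefix) sprintf("%s%03d", prefix, seq_len(n))

#' Simulate the cell-line panel
#'
#' @param design A [design_cell_line_panel()] design.
#' @return A list with `ct` (a [ct_matrix()]), `annotation` (a
#'   [sample_annotation()] with genotype, condition, replicate) and
#'   `truth` (planted assay sets and the full effect map).
#' @export
simulate_cell_line_panel <- function(design = design_cell_line_panel()) {
  stopifnot(inherits(design, "synthetic_design"),
            design$kind == "cell_line_panel")
  set.seed(design$seed)
  assays <- .assay_ids(design$n_assays, "g")
  conditions <- c("SCF+", "SCF-", "imatinib")
  lines <- names(design$replicates)
  if (any(design$replicates == 0)) stop("line with 0 samples", call. = FALSE)

  # planted assay sets (disjoint)
  idx <- sample(design$n_assays)
  shared <- assays[idx[seq_len(design$n_shared)]]
  d6_spec <- assays[idx[design$n_shared + seq_len(design$n_d6)]]
  d54_spec <- assays[idx[design$n_shared + design$n_d6 +
                           seq_len(design$n_d54)]]
  cond_spec <- assays[idx[design$n_shared + design$n_d6 + design$n_d54 +
                            seq_len(design$n_condition)]]
  sign_of <- stats::setNames(sample(c(-1, 1), design$n_assays, TRUE), assays)

  # per-line effect vectors (cycles, + = up-regulated = lower Ct)
  eff <- matrix(0, design$n_assays, length(lines),
                dimnames = list(assays, lines))
  hemi <- design$hemi_effect
  het <- design$het_ratio * hemi
  eff[shared, "D6"] <- eff[shared, "D54"] <- (sign_of * hemi)[shared]
  eff[shared, "WT/D6"] <- eff[shared, "WT/D54"] <- (sign_of * het)[shared]
  eff[d6_spec, "D6"] <- (sign_of * hemi)[d6_spec]
  eff[d6_spec, "WT/D6"] <- (sign_of * het)[d6_spec]
  eff[d54_spec, "D54"] <- (sign_of * hemi)[d54_spec]
  eff[d54_spec, "WT/D54"] <- (sign_of * het)[d54_spec]

  cond_eff <- matrix(0, design$n_assays, length(conditions),
                     dimnames = list(assays, conditions))
  cond_eff[cond_spec, "SCF-"] <- (sign_of * design$condition_effect)[cond_spec]
  cond_eff[cond_spec, "imatinib"] <-
    (sign_of * 0.8 * design$condition_effect)[cond_spec]

  baseline <- stats::runif(design$n_assays, design$baseline_range[1],
                           design$baseline_range[2])

  ann <- do.call(rbind, lapply(lines, function(ln)
    do.call(rbind, lapply(conditions, function(cd)
      data.frame(genotype = ln, condition = cd,
                 replicate = seq_len(design$replicates[[ln]]))))))
  ann$sample <- sprintf("%s_%s_r%d", gsub("/", ".", ann$genotype),
                        gsub("[+]", "p", sub("-", "m", ann$condition)),
                        ann$replicate)
  n_samples <- nrow(ann)

  max_rep <- max(design$replicates)
  batch <- matrix(stats::rnorm(design$n_assays * max_rep, 0,
                               design$batch_sd),
                  design$n_assays, max_rep)
  card <- stats::setNames(
    sprintf("card%02d", ceiling(seq_len(n_samples) / design$samples_per_card)),
    ann$sample)
  offset <- stats::setNames(
    stats::rnorm(length(unique(card)), 0, design$card_offset_sd),
    unique(card))

  values <- matrix(NA_real_, design$n_assays, n_samples,
                   dimnames = list(assays, ann$sample))
  for (s in seq_len(n_samples)) {
    values[, s] <- baseline - eff[, ann$genotype[s]] -
      cond_eff[, ann$condition[s]] + batch[, ann$replicate[s]] +
      offset[card[ann$sample[s]]] +
      .well_noise(design$n_assays, design$noise_sd, design$noise_df)
  }
  values[values > design$detect_limit] <- NA_real_
  values <- .apply_dropout(pmin(pmax(values, 0), 50), design$dropout_rate)

  list(ct = ct_matrix(values, card = card),
       annotation = sample_annotation(
         ann[, c("sample", "genotype", "condition", "replicate")]),
       truth = list(shared = shared, d6_specific = d6_spec,
                    d54_specific = d54_spec, condition_responsive = cond_spec,
                    effects = eff, condition_effects = cond_eff,
                    baseline = stats::setNames(baseline, assays),
                    design = design))
}

#' Tumour-cohort design
#'
#' Default design ("paper-like" preset): 384 miRNA assays plus a stable
#' reference assay (ETV6-like, SD ~0.2 cycles across tumours) and an
#' unstable pseudo-reference (18S-like, SD ~2 cycles) to exercise the
#' choice of normalizer; 6 homozygous and 13 heterozygous KIT exon-11
#' tumours, one 384-well card each. A planted signature of
#' `n_signature` assays separates the zygosity groups by
#' `signature_effect` cycles (random signs). On top of technical noise,
#' each tumour perturbs every miRNA assay independently with SD
#' `tumor_scatter_sd` — the tumour-to-tumour biological heterogeneity of
#' FFPE cohorts, which is what keeps the signature invisible to
#' unsupervised clustering over all assays.
#'
#' @param n_assays Number of miRNA assays.
#' @param n_hom,n_het Tumours per zygosity group.
#' @param n_signature Number of signature assays.
#' @param signature_effect Homozygous-vs-heterozygous shift in cycles.
#' @param noise_sd Technical noise SD (cycles).
#' @param tumor_scatter_sd Per-(tumour, assay) biological scatter SD
#'   (cycles); applies to miRNA assays, not the reference assays.
#' @param stable_ref_sd,unstable_ref_sd Across-tumour SD of the stable
#'   and unstable reference assays (cycles).
#' @param card_offset_sd SD of per-card (= per-tumour) offsets (cycles).
#' @param baseline_range Per-assay baseline Ct range (cycles).
#' @param detect_limit Instrument limit (cycles).
#' @param noise_df Noise degrees of freedom: `Inf` for Gaussian, finite
#'   for variance-matched Student-t heavy tails.
#' @param dropout_rate Independent random non-detect probability per well
#'   (default 0; non-detects otherwise arise only from the instrument
#'   limit).
#' @param seed Integer seed.
#' @return A list of class `synthetic_design`.
#' @export
design_tumor_cohort <- function(n_assays = 384, n_hom = 6, n_het = 13,
                                n_signature = 13, signature_effect = 2.0,
                                noise_sd = 0.3, tumor_scatter_sd = 1.0,
                                stable_ref_sd = 0.2, unstable_ref_sd = 2.0,
                                card_offset_sd = 0.5,
                                baseline_range = c(24, 33),
                                detect_limit = 40, noise_df = Inf,
                                dropout_rate = 0, seed = 1L) {
  stopifnot(n_hom >= 1, n_het >= 1, n_signature <= n_assays,
            noise_sd >= 0, tumor_scatter_sd >= 0, noise_df > 2,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(kind = "tumor_cohort", n_assays = n_assays, n_hom = n_hom,
                 n_het = n_het, n_signature = n_signature,
                 signature_effect = signature_effect, noise_sd = noise_sd,
                 tumor_scatter_sd = tumor_scatter_sd,
                 stable_ref_sd = stable_ref_sd,
                 unstable_ref_sd = unstable_ref_sd,
                 card_offset_sd = card_offset_sd,
                 baseline_range = baseline_range,
                 detect_limit = detect_limit, noise_df = noise_df,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Simulate the tumour cohort
#'
#' @param design A [design_tumor_cohort()] design.
#' @return A list with `ct` (miRNA assays plus reference assays `ETV6`
#'   and `RN18S`, class `"control"`), `annotation` (zygosity and
#'   mutation class) and `truth` (signature assay ids, effect map,
#'   design).
#' @export
simulate_tumor_cohort <- function(design = design_tumor_cohort()) {
  stopifnot(inherits(design, "synthetic_design"),
            design$kind == "tumor_cohort")
  set.seed(design$seed)
  assays <- .assay_ids(design$n_assays, "miR")
  samples <- c(sprintf("hom%02d", seq_len(design$n_hom)),
               sprintf("het%02d", seq_len(design$n_het)))
  zyg <- stats::setNames(rep(c("homozygous", "heterozygous"),
                             c(design$n_hom, design$n_het)), samples)

  signature <- sort(sample(assays, design$n_signature))
  sgn <- stats::setNames(sample(c(-1, 1), design$n_signature, TRUE),
                         signature)
  eff <- matrix(0, design$n_assays, length(samples),
                dimnames = list(assays, samples))
  eff[signature, zyg == "homozygous"] <- sgn * design$signature_effect

  baseline <- stats::runif(design$n_assays, design$baseline_range[1],
                           design$baseline_range[2])
  card <- stats::setNames(sprintf("cardT%02d", seq_along(samples)), samples)
  offset <- stats::rnorm(length(samples), 0, design$card_offset_sd)

  values <- matrix(NA_real_, design$n_assays, length(samples),
                   dimnames = list(assays, samples))
  for (s in seq_along(samples)) {
    values[, s] <- baseline - eff[, s] + offset[s] +
      stats::rnorm(design$n_assays, 0, design$tumor_scatter_sd) +
      .well_noise(design$n_assays, design$noise_sd, design$noise_df)
  }
  # reference assays ride on the same card offsets
  etv6 <- 25 + offset + stats::rnorm(length(samples), 0, design$stable_ref_sd)
  rn18s <- 12 + offset + stats::rnorm(length(samples), 0,
                                      design$unstable_ref_sd)
  values <- rbind(values, ETV6 = etv6, RN18S = rn18s)
  values[values > design$detect_limit] <- NA_real_
  values <- .apply_dropout(pmin(pmax(values, 0), 50), design$dropout_rate)

  assay_class <- stats::setNames(
    c(rep("miRNA", design$n_assays), "control", "control"), rownames(values))
  ann <- data.frame(sample = samples, zygosity = unname(zyg),
                    mutation_class = "KIT_ex11",
                    replicate = 1L)
  list(ct = ct_matrix(values, card = card, assay_class = assay_class),
       annotation = sample_annotation(ann),
       truth = list(signature = signature, signs = sgn, effects = eff,
                    baseline = stats::setNames(baseline, assays),
                    design = design))
}

#' High-density array design
#'
#' Log-normal probe intensities on a set of arrays in two groups, with
#' 100 negative-control probes at low intensity, per-array scale factors
#' (what median normalization must undo) and planted fold-change genes:
#' `n_strong` genes at `strong_fold` and `n_weak` at `weak_fold`
#' (up-regulated in group B), against `n_genes` total target probes.
#'
#' @param n_genes Number of target probes.
#' @param n_neg Number of negative-control probes.
#' @param n_a,n_b Arrays per group.
#' @param n_strong,strong_fold,n_weak,weak_fold Planted differential
#'   genes and their fold changes.
#' @param noise_sdlog Multiplicative (log-normal) noise SD on the log
#'   scale (0.05 ~ 5% coefficient of variation).
#' @param scale_sdlog SD of log array scale factors.
#' @param planted_meanlog Mean log intensity of planted genes (kept above
#'   background so the amplitude criterion is about the biology, not the
#'   abundance draw).
#' @param neg_meanlog,neg_sdlog Negative-control intensity distribution.
#' @param seed Integer seed.
#' @return A list of class `synthetic_design`.
#' @export
design_high_density <- function(n_genes = 200, n_neg = 100, n_a = 3, n_b = 3,
                                n_strong = 20, strong_fold = 2.5,
                                n_weak = 20, weak_fold = 1.2,
                                noise_sdlog = 0.05, scale_sdlog = 0.3,
                                planted_meanlog = log(2),
                                neg_meanlog = log(0.08), neg_sdlog = 0.3,
                                seed = 1L) {
  stopifnot(n_strong + n_weak <= n_genes, n_neg >= 2)
  structure(list(kind = "high_density", n_genes = n_genes, n_neg = n_neg,
                 n_a = n_a, n_b = n_b, n_strong = n_strong,
                 strong_fold = strong_fold, n_weak = n_weak,
                 weak_fold = weak_fold, noise_sdlog = noise_sdlog,
                 scale_sdlog = scale_sdlog,
                 planted_meanlog = planted_meanlog,
                 neg_meanlog = neg_meanlog, neg_sdlog = neg_sdlog,
                 n_assays = n_genes, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Simulate high-density arrays
#'
#' @param design A [design_high_density()] design.
#' @return A list with `ia` (an [intensity_array()], raw), `group_a` and
#'   `group_b` (array ids) and `truth` (strong/weak planted gene ids,
#'   per-array scale factors).
#' @export
simulate_high_density <- function(design = design_high_density()) {
  stopifnot(inherits(design, "synthetic_design"),
            design$kind == "high_density")
  set.seed(design$seed)
  genes <- .assay_ids(design$n_genes, "p")
  negs <- .assay_ids(design$n_neg, "neg")
  arrays <- c(sprintf("A%d", seq_len(design$n_a)),
              sprintf("B%d", seq_len(design$n_b)))
  in_b <- rep(c(FALSE, TRUE), c(design$n_a, design$n_b))

  strong <- genes[seq_len(design$n_strong)]
  weak <- genes[design$n_strong + seq_len(design$n_weak)]
  meanlog <- stats::rnorm(design$n_genes, 0, 1)
  meanlog[genes %in% c(strong, weak)] <-
    stats::rnorm(design$n_strong + design$n_weak, design$planted_meanlog, 0.3)
  fold <- stats::setNames(rep(1, design$n_genes), genes)
  fold[strong] <- design$strong_fold
  fold[weak] <- design$weak_fold

  scale_f <- exp(stats::rnorm(length(arrays), 0, design$scale_sdlog))
  raw <- matrix(0, design$n_genes + design$n_neg, length(arrays),
                dimnames = list(c(genes, negs), arrays))
  for (j in seq_along(arrays)) {
    mu <- meanlog + if (in_b[j]) log(fold) else 0
    raw[genes, j] <- exp(mu + stats::rnorm(design$n_genes, 0,
                                           design$noise_sdlog)) * scale_f[j]
    raw[negs, j] <- exp(stats::rnorm(design$n_neg, design$neg_meanlog,
                                     design$neg_sdlog)) * scale_f[j]
  }
  probe_class <- stats::setNames(
    rep(c("target", "negative_control"), c(design$n_genes, design$n_neg)),
    rownames(raw))
  list(ia = intensity_array(raw, probe_class = probe_class),
       group_a = arrays[!in_b], group_b = arrays[in_b],
       truth = list(strong = strong, weak = weak,
                    scale_factors = stats::setNames(scale_f, arrays),
                    design = design))
}
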