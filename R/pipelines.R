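# End-to-end workflows: the two analyses the package exists for, wired
# from the individual stages. Both take a Ct matrix plus annotation (real
# or simulated) and return the dendrograms together with quantitative
# topology reports, so the qualitative claims ("heterozygous clusters
# with WT", "zygosity separates only under supervision") become numbers.

#' Cell-line panel analysis: cut-off, global-median ddCt, control filter,
#' clustering
#'
#' Runs the low-density-card workflow on a genotype panel: Ct cut-off,
#' per-card global-median delta-Ct, mean-centred delta-delta-Ct,
#' exclusion of assays that respond to culture conditions in the
#' empty-vector control line (nonspecific filter), then unsupervised
#' hierarchical clustering of the KIT-expressing lines within one
#' condition, with monophyly/ARI topology checks of the expected
#' zygosity grouping (WT with heterozygous, hemizygous apart).
#'
#' @param ct A [ct_matrix()].
#' @param annotation A [sample_annotation()] with `genotype`, `condition`.
#' @param cutoff Ct cut-off in cycles (default 35).
#' @param filter_alpha Alpha of the control-line nonspecific ANOVA filter.
#' @param condition Condition whose samples are clustered (default
#'   `"SCF+"`).
#' @param control_genotype Label of the empty-vector line (default
#'   `"MIGR"`).
#' @param linkage Linkage for [hierarchical_cluster()].
#' @return A list: `rq` (full RQ matrix), `filter` (selection_result),
#'   `tree` (hclust), `topology` (topology_report at k = 3 over
#'   WT+het / D6 / D54), `wt_subtree_ok` (does the smallest subtree
#'   holding all WT samples hold all heterozygous and no hemizygous
#'   samples).
#' @export
analyze_cell_line_panel <- function(ct, annotation, cutoff = 35,
                                    filter_alpha = 0.05,
                                    condition = "SCF+",
                                    control_genotype = "MIGR",
                                    linkage = "average") {
  ann <- annotation
  ct <- apply_ct_cutoff(ct, cutoff)
  rq <- suppressWarnings(delta_delta_ct(delta_ct(ct, "card_median")))

  ctrl <- ann$sample[ann$genotype == control_genotype]
  conds <- stats::setNames(ann$condition, ann$sample)[ctrl]
  filt <- nonspecific_filter(rq, conds, alpha = filter_alpha)

  keep_samples <- ann$sample[ann$condition == condition &
                               ann$genotype != control_genotype]
  expr <- log2_expression(rq)[filt$retained, keep_samples, drop = FALSE]
  tree <- hierarchical_cluster(expr, linkage = linkage)

  genotype <- stats::setNames(ann$genotype, ann$sample)[keep_samples]
  zygroup <- stats::setNames(
    ifelse(genotype %in% c("WT", "WT/D6", "WT/D54"), "WT+het", genotype),
    names(genotype))
  topo <- topology_checks(tree, zygroup, k = 3)

  wt <- names(genotype)[genotype == "WT"]
  het <- names(genotype)[genotype %in% c("WT/D6", "WT/D54")]
  hemi <- names(genotype)[genotype %in% c("D6", "D54")]
  st <- smallest_subtree(tree, wt)
  wt_subtree_ok <- all(het %in% st) && !any(hemi %in% st)

  list(rq = rq, filter = filt, tree = tree, topology = topo,
       wt_subtree_ok = wt_subtree_ok, condition = condition)
}

#' Tumour-cohort analysis: supervised vs unsupervised zygosity clustering
#'
#' Runs the tumour workflow: Ct cut-off (37 by default, FFPE material),
#' per-card global-median delta-delta-Ct over the miRNA assays, then both
#' an unsupervised clustering over all assays and a supervised clustering
#' on the assays retained by per-assay ANOVA between zygosity groups,
#' each scored for zygosity monophyly.
#'
#' @param ct A [ct_matrix()] including miRNA assays (class `"miRNA"`).
#' @param annotation A [sample_annotation()] with `zygosity`.
#' @param cutoff Ct cut-off in cycles (default 37).
#' @param alpha ANOVA retention threshold for the supervised stage.
#' @param linkage Linkage for [hierarchical_cluster()].
#' @return A list: `rq`, `selection` (selection_result of the supervised
#'   ANOVA), `supervised` / `unsupervised` (hclust trees),
#'   `supervised_separates` / `unsupervised_separates` (do both zygosity
#'   groups come out monophyletic), and the two topology reports.
#' @export
analyze_tumor_cohort <- function(ct, annotation, cutoff = 37, alpha = 0.05,
                                 linkage = "average") {
  ann <- annotation
  ct <- apply_ct_cutoff(ct, cutoff)
  mirna <- names(ct$assay_class)[ct$assay_class == "miRNA"]
  ctm <- ct_matrix(ct$values[mirna, , drop = FALSE], card = ct$card,
                   assay_class = ct$assay_class[mirna])
  rq <- suppressWarnings(delta_delta_ct(delta_ct(ctm, "card_median")))

  zyg <- stats::setNames(ann$zygosity, ann$sample)
  unsup <- hierarchical_cluster(rq, linkage = linkage)
  topo_unsup <- topology_checks(unsup, zyg, k = 2)
  sup <- supervised_cluster(rq, zyg, alpha = alpha, linkage = linkage)
  topo_sup <- topology_checks(sup, zyg, k = 2)

  list(rq = rq, selection = attr(sup, "selection"),
       supervised = sup, unsupervised = unsup,
       supervised_separates = all(topo_sup$monophyly),
       unsupervised_separates = all(topo_unsup$monophyly),
       topology_supervised = topo_sup, topology_unsupervised = topo_unsup)
}
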