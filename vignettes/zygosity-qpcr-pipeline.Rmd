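---
title: "Quantifying KIT-mutation zygosity signatures from low-density qPCR arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying KIT-mutation zygosity signatures from low-density qPCR arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygoct)
```

## The problem

Gastrointestinal stromal tumours (GIST) are driven by activating mutations
in the KIT or PDGFRA receptor kinases. Most tumours are heterozygous (one
mutant, one wild-type allele), but a minority lose the wild-type allele
(hemizygous/homozygous), and that loss is associated with more aggressive
disease. A natural question is whether zygosity leaves a measurable mark
on the transcriptome: do cells carrying only a mutant allele express a
different mRNA and miRNA programme than cells that still carry the
wild-type allele?

The measurement instrument of choice at this scale is the TaqMan
low-density array (TLDA): a microfluidic card running ~96–384 parallel
qPCR assays per sample, read out as threshold cycles (Ct; one cycle
difference = a twofold difference in template). TLDA data come with their
own pathologies — late unreliable Ct values, "Undetermined" non-detects,
card-to-card offsets, and reference genes that turn out not to be stable —
and this package implements a complete, tested quantification and
classification stack for them:

1. Ct cut-off filtering (`apply_ct_cutoff()`),
2. per-card global-median normalization, the "virtual housekeeping gene"
   (`card_median_correction()`, `delta_ct()`),
3. ΔΔCt relative quantification against the per-assay mean
   (`delta_delta_ct()`),
4. single-reference-gene quantification, Ntarget = 2^(Ct_ref − Ct_target),
   with per-tumour correcting factors (`ntarget_reference_gene()`,
   `tumor_correcting_factors()`),
5. reference-gene stability ranking (`genorm_stability()`),
6. control-line nonspecific filtering and supervised ANOVA / PCA feature
   selection (`nonspecific_filter()`, `supervised_anova_select()`,
   `pca_gene_selection()`),
7. hierarchical clustering and 2-component PCA of samples with
   quantitative topology checks (`hierarchical_cluster()`,
   `supervised_cluster()`, `pca_scores()`, `topology_checks()`),
8. the high-density array stage that nominates candidate genes in the
   first place (`median_normalize_array()`, `detection_threshold()`,
   `select_differential_genes()`), and
9. synthetic data generators with ground truth for every stage
   (`simulate_cell_line_panel()`, `simulate_tumor_cohort()`,
   `simulate_high_density()`).

## The quantification model

**Cut-off.** Ct values beyond a cut-off are discarded as non-detects
(35 cycles for cell-line material, 37 for FFPE tumours, both arguments).
Non-detects are excluded from every downstream statistic; they are never
imputed.

**Global-median normalization.** For each card *j* with median present Ct
*m<sub>j</sub>*, every well is corrected by `Ct − (m_j − target)`, where
the target is by default the median of the per-card medians (robust to
cards with different non-detect loads; an explicit target value is also
accepted). After correction every card shares the same median exactly —
a "virtual housekeeping gene" that is perfectly stable by construction.
ΔCt is then the corrected Ct minus that shared median, equivalently the
raw Ct minus its own card median (the two routes commute, and the package
tests that).

**ΔΔCt with a mean reference.** For each assay,
`ΔΔCt = ΔCt − mean(ΔCt across samples)` and `RQ = 2^(−ΔΔCt)`. Using the
per-assay mean instead of a designated calibrator sample avoids hanging
every quantity off one noisy sample, and makes the per-assay geometric
mean of RQ exactly 1 — an invariant the test suite enforces to 1e-9.
Signs are fixed throughout so that higher expression means larger RQ.
Amplification efficiency is assumed to be 2 (no efficiency correction).

**Reference-gene mode.** When a biological normalizer is trusted
(e.g. ETV6 in tumours, where 18S proves unstable),
`Ntarget = 2^(Ct_ref − Ct_target)` per sample; per-tumour correcting
factors `F_j = mean(Ct_ref) − Ct_ref(j)` (grand mean over tumours) are
added to every assay so that the reference becomes exactly stable across
tumours. `genorm_stability()` ranks candidate normalizers by the geNorm
M statistic — the mean SD across samples of a gene's pairwise log2
ratios with every other candidate — with iterative exclusion down to a
floor of two genes and the pairwise-variation record V(n).

**Group statistics on the log2 scale.** All ANOVA/clustering/PCA stages
operate on log2 RQ (= −ΔΔCt): the Ct scale is where qPCR noise is
closest to Gaussian. The ANOVA is the classic one-way fixed-effects test
(Welch behind `var_equal = FALSE`); an assay with zero variance is
defined to have p = 1 (no evidence of effect). Matching the original
workflow, p-values are used at raw alpha without multiple-testing
correction; `p.adjust()` can of course be applied to the returned
per-assay p-values by the user.

## Clustering and topology checks

Distances are Euclidean on log2 RQ, so they have cycle units. Missing
cells are handled pairwise: the squared distance over jointly present
assays is rescaled by `total/shared` so pairs with different non-detect
loads stay comparable (with no missing data this is the plain Euclidean
distance). Linkage defaults to average (UPGMA); complete, single and
Ward are available, and conclusions about dendrogram topology should be
checked for linkage sensitivity. Samples are sorted by id before
clustering so the tree is order-invariant.

Instead of reading dendrograms by eye, `topology_checks()` reports, per
group, whether some subtree contains exactly that group (monophyly), the
smallest enclosing subtree of each group, pairwise subtree disjointness,
and the adjusted Rand index between the group labels and the tree cut at
k clusters. `pca_scores()` adds the 2-component PCA picture with
deterministic loading signs, and `score_silhouette()` summarizes group
separation in the score plane.

## What the synthetic generators emulate

The generative model is deliberately transparent:

`Ct = baseline(assay) − effect(assay, group) + card_offset(card) +
batch(replicate, assay) + N(0, noise_sd)`,

with non-detects arising mechanistically whenever the simulated Ct
exceeds the instrument limit (40 cycles), so cut-off handling is
exercised realistically rather than by independent dropout.

**Cell-line preset** (`design_cell_line_panel()`): 94 assays; genotypes
MIGR (empty vector), WT, D6, D54 (hemizygous KIT exon-11 deletions) and
WT/D6, WT/D54 (heterozygous) under SCF+, SCF− and imatinib; replicates
3/3/3/3/2/2 per condition. A 20-assay shared mutation signature is
planted at 1.5 cycles in hemizygous lines and scaled by 0.15 in
heterozygous ones (so heterozygous profiles hug WT); D6 and D54 differ
on disjoint 8-assay sets; 15 assays respond to the culture condition in
every line including MIGR — the targets the control-line filter must
remove. Replicate *r* of every line shares a per-(replicate, assay)
batch term (SD 0.3 cycles): a "complete replicate" is one experiment run
across all lines, and that shared batch structure is what makes WT and
heterozygous samples interleave within their joint clade rather than
forming genotype-pure islands. Technical noise is 0.3 cycles, card
offsets (4 samples per card) 0.5 cycles.

**Tumour preset** (`design_tumor_cohort()`): 384 miRNA assays on one
card per tumour, 6 homozygous vs 13 heterozygous KIT exon-11 tumours,
plus a stable ETV6-like reference (SD 0.2 cycles) and an unstable
18S-like pseudo-reference (SD 2 cycles) to exercise normalizer choice. A
13-miRNA zygosity signature is planted at 2.0 cycles. On top of 0.3
cycles of technical noise, every tumour perturbs every miRNA assay
independently with SD 1.0 cycles — the tumour-to-tumour biological
heterogeneity of FFPE cohorts. That scatter value was calibrated (over
0.8/0.9/1.0, 50 simulations each) as the smallest value reproducing the
qualitative behaviour the pipeline is meant to expose: ANOVA-supervised
clustering separates zygosity groups while unsupervised clustering over
all 384 assays does not. The true effect sizes in real cohorts are
unknown (the raw TLDA data behind the original studies are not publicly
deposited), so the presets are reconstructions tuned to qualitative
topology, not measurements — recovery rates on them say the pipeline's
machinery works, not that real tumours carry effects of this size.

The generators do **not** emulate: correlated co-regulation among
non-signature assays, amplification-efficiency differences between
assays, plate-position effects within a card, or heavy-tailed outliers
(a heavy-tailed noise option exists for robustness checks). Passing
tests on synthetic panels therefore demonstrate correctness of the
algorithms under the declared model, not robustness to every real-data
pathology.

**High-density preset** (`design_high_density()`): log-normal target
intensities over 200 genes and 100 low-intensity negative-control
probes, per-array scale factors (what median normalization must undo),
5% multiplicative noise, and planted 2.5-fold and 1.2-fold genes
(up in group B) with abundance kept above the amplitude threshold so
the selection is judged on fold change, not on the abundance draw.

## Numerical choices and edge cases

- Non-detect spellings accepted on input: `"Undetermined"`,
  `"undetermined"`, `"NA"`, empty. Decimal commas are honoured only
  behind an explicit `decimal = "comma"` flag — locale guessing silently
  corrupts Ct values.
- The wide Ct dialect requires a sample→card sidecar; card identity
  cannot be inferred from the table and normalization is per card.
- RQ tables are written at 15 significant digits: write→read round trips
  reproduce values to better than 1e-12 and a second write is
  byte-identical.
- Mann–Whitney switches from exact enumeration to the tie-corrected
  normal approximation above 12 observations or in the presence of ties;
  Fisher's test is always exact two-sided. Both are verified against
  brute-force enumeration oracles in the test suite.
- Logistic fits detect complete/quasi-complete separation from the
  fitted probabilities and report the factor as non-estimable instead of
  forwarding the optimizer's arbitrary large coefficient (sparse
  categories in small cohorts make this common).
- geNorm ties in M break lexicographically by gene id; iterative
  exclusion stops at two genes.
- PCA loading signs are fixed by making the largest-magnitude loading of
  each component positive; gene selection weights loadings by component
  scale so degenerate components contribute nothing.
- Detection calls: absent strictly below the threshold (mean + 3 SD of
  negative controls), marginal in [1, 1.2) × threshold, present above —
  a probe exactly at the threshold is not absent. The "present or
  marginal" requirement in fold-change selection defaults to "in all
  samples of at least one compared group" (a gene must be above
  background somewhere); the strict both-groups rule is available via
  `call_rule = "all_samples"`.
- Zero intensities are floored at 0.01 before ratios so fold changes are
  finite; affected genes are flagged.

## Problem sizes used in the automated checks

The test suite and `scripts/acceptance.R` run the pipeline at the study's
own scale: 94-assay × 48-sample cell-line panels and 386-assay ×
19-tumour cohorts, with 50–100 independent simulations per recovery rate,
200 random matrices for the normalization-exactness laws, 1000 null
assays for ANOVA calibration, and full enumeration oracles up to 5+5
observations (Mann–Whitney) and table totals of 30 (Fisher). These sizes
give rate estimates with standard errors of a few percent while keeping
a full run in the order of a minute or two.

## Known limitations

- The PCA-based "frequently deregulated gene" selection is a
  reconstruction (loading magnitude on the first two components); the
  original analyses did not specify a criterion.
- Whether the original per-card correction targeted the median of card
  medians or a fixed constant is not recoverable; both are supported,
  median-of-medians is the default.
- Multivariate logistic regression is out of scope (no usable detail to
  reproduce); the univariate fits plus Fisher tests cover the clinical
  association table.
- No amplification-efficiency correction and no non-detect imputation;
  assays failing their preconditions are skipped and reported, never
  silently filled in.
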