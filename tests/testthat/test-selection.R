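log2_rq <- function(expr) rq_matrix(2^expr)   # expr = log2 expression

test_that("nonspecific filter excludes condition-responsive control assays", {
  set.seed(14)
  conds <- rep(c("SCF+", "SCF-", "imatinib"), each = 3)
  samples <- sprintf("MIGR_%d", seq_along(conds))
  # planted 2-cycle condition effect, noise SD 0.1 (well powered);
  # a flat assay; and an exactly constant assay (p = 1 by convention)
  eff <- ifelse(conds == "SCF+", 0, 2)
  expr <- rbind(resp = eff + rnorm(9, 0, 0.1),
                flat = rnorm(9, 0, 0.1),
                const = rep(1.5, 9))
  colnames(expr) <- samples
  sel <- nonspecific_filter(log2_rq(expr), setNames(conds, samples),
                            alpha = 0.05)
  expect_false("resp" %in% sel$retained)
  expect_true(all(c("flat", "const") %in% sel$retained))
  p <- setNames(sel$stats$p.value, sel$stats$assay)
  expect_equal(unname(p["const"]), 1)
  expect_lt(unname(p["resp"]), 0.05)
  # alpha is honoured exactly: retained = {p >= alpha}
  expect_setequal(sel$retained, names(p)[p >= 0.05])
  # replicate requirement enforced
  expect_error(
    nonspecific_filter(log2_rq(expr[, 1:4]),
                       setNames(conds[1:4], samples[1:4])),
    "fewer than 2 control replicates")
})

test_that("the planted-effect exclusion p matches the F-distribution", {
  set.seed(14)
  conds <- rep(c("A", "B", "C"), each = 2)
  v <- ifelse(conds == "A", 0, 2) + rnorm(6, 0, 0.1)
  expr <- matrix(v, 1, dimnames = list("g", sprintf("s%d", 1:6)))
  sel <- nonspecific_filter(log2_rq(expr), setNames(conds, colnames(expr)))
  grand <- mean(v)
  gm <- tapply(v, conds, mean)
  ssb <- sum(2 * (gm - grand)^2)
  ssw <- sum((v - gm[conds])^2)
  f <- (ssb / 2) / (ssw / 3)
  expect_equal(sel$stats$p.value, pf(f, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("supervised ANOVA selection retains discriminating assays only", {
  set.seed(6)
  groups <- setNames(rep(c("hom", "het"), c(6, 13)), sprintf("t%02d", 1:19))
  expr <- matrix(rnorm(20 * 19, 0, 0.3), 20,
                 dimnames = list(sprintf("m%02d", 1:20), names(groups)))
  expr[1:4, groups == "hom"] <- expr[1:4, groups == "hom"] + 1.5
  sel <- supervised_anova_select(log2_rq(expr), groups, alpha = 0.05)
  expect_true(all(sprintf("m%02d", 1:4) %in% sel$retained))
  # two identical groups retain nothing
  expr2 <- matrix(rep(rnorm(19, 0, 1), each = 5), 5,
                  dimnames = list(sprintf("g%d", 1:5), names(groups)))
  sel2 <- supervised_anova_select(log2_rq(expr2), groups)
  expect_length(sel2$retained, 0)
  # retained set shrinks monotonically as alpha decreases
  alphas <- c(0.2, 0.1, 0.05, 0.01)
  sets <- lapply(alphas, function(a)
    supervised_anova_select(log2_rq(expr), groups, alpha = a)$retained)
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("assays unusable for ANOVA are skipped with a reason", {
  groups <- setNames(rep(c("a", "b"), each = 3), sprintf("s%d", 1:6))
  expr <- matrix(rnorm(12), 2,
                 dimnames = list(c("ok", "halfmasked"), names(groups)))
  expr["halfmasked", groups == "b"] <- NA
  sel <- supervised_anova_select(log2_rq(expr), groups)
  expect_identical(sel$skipped$assay, "halfmasked")
  expect_match(sel$skipped$reason, "usable groups")
  expect_true("ok" %in% sel$stats$assay[!is.na(sel$stats$p.value)])
})

test_that("PCA selection finds the genes that carry the variance", {
  # one varying gene among constants
  expr <- matrix(0.01, 5, 6,
                 dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:6)))
  expr["g3", ] <- c(-3, -2, -1, 1, 2, 3)
  sel <- pca_gene_selection(log2_rq(expr), k = 1)
  expect_identical(sel$retained, "g3")
  # k = all genes selects everything
  expect_setequal(pca_gene_selection(log2_rq(expr), k = 5)$retained,
                  rownames(expr))
  # two orthogonal planted patterns rank above noise genes
  set.seed(9)
  n <- 12
  p1 <- rep(c(-1, 1), each = n / 2)
  p2 <- rep(c(-1, 1), n / 2)
  expr2 <- rbind(
    matrix(rep(p1, each = 4), 4, byrow = FALSE) * 2 +
      matrix(rnorm(4 * n, 0, 0.1), 4),
    matrix(rep(p2, each = 4), 4, byrow = FALSE) * 2 +
      matrix(rnorm(4 * n, 0, 0.1), 4),
    matrix(rnorm(12 * n, 0, 0.1), 12))
  dimnames(expr2) <- list(c(sprintf("sig%d", 1:8), sprintf("noise%d", 1:12)),
                          sprintf("s%d", seq_len(n)))
  sel2 <- pca_gene_selection(log2_rq(expr2), k = 8)
  expect_setequal(sel2$retained, sprintf("sig%d", 1:8))
  expect_error(pca_gene_selection(log2_rq(expr2 * 0 + 1), k = 2),
               "constant")
})

test_that("PCA selection is invariant to sample order and per-gene shifts", {
  set.seed(17)
  expr <- matrix(rnorm(10 * 8), 10,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:8)))
  base <- pca_gene_selection(log2_rq(expr), k = 3)
  perm <- pca_gene_selection(log2_rq(expr[, sample(8)]), k = 3)
  expect_identical(base$retained, perm$retained)
  shifted <- expr
  shifted["g4", ] <- shifted["g4", ] + 5
  expect_identical(pca_gene_selection(log2_rq(shifted), k = 3)$retained,
                   base$retained)
})
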