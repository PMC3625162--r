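test_that("rescaled distance reduces to Euclidean without missingness", {
  m <- matrix(c(0, 0, 3, 4), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  d <- rescaled_euclidean_dist(m)
  expect_equal(as.numeric(d), 5)
  set.seed(12)
  m2 <- matrix(rnorm(50), 10, 5,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  expect_equal(as.matrix(rescaled_euclidean_dist(m2)),
               as.matrix(dist(t(m2))), tolerance = 1e-12)
})

test_that("missing cells use jointly present assays with sqrt rescaling", {
  m <- matrix(c(0, 0, 1, 3, 4, NA), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  d <- rescaled_euclidean_dist(m)
  expect_equal(as.numeric(d), sqrt(25 * 3 / 2))
  m[, 2] <- NA
  expect_error(rescaled_euclidean_dist(m), "share no present assay")
})

test_that("identical samples merge at height zero, deterministically", {
  m <- matrix(c(1, 2, 1, 2, 5, 9), 2, 3,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  h <- hierarchical_cluster(m)
  expect_equal(h$height[1], 0)
  expect_setequal(smallest_subtree(h, c("s1", "s2")), c("s1", "s2"))
})

test_that("the dendrogram is invariant to input sample order", {
  set.seed(19)
  m <- matrix(rnorm(8 * 10), 8, 10,
              dimnames = list(sprintf("g%d", 1:8), sprintf("s%02d", 1:10)))
  h1 <- hierarchical_cluster(m)
  h2 <- hierarchical_cluster(m[, sample(10)])
  expect_identical(h1$labels, h2$labels)
  expect_equal(h1$height, h2$height)
  expect_identical(h1$merge, h2$merge)
})

test_that("supervised clustering with alpha 1 equals unsupervised", {
  set.seed(23)
  m <- matrix(rnorm(12 * 8), 12, 8,
              dimnames = list(sprintf("g%d", 1:12), sprintf("s%d", 1:8)))
  groups <- setNames(rep(c("a", "b"), each = 4), colnames(m))
  hu <- hierarchical_cluster(m)
  hs <- supervised_cluster(m, groups, alpha = 1)
  expect_equal(hs$merge, hu$merge)
  expect_equal(hs$height, hu$height)
  expect_s3_class(attr(hs, "selection"), "selection_result")
  expect_identical(sort(attr(hs, "selection")$retained), sort(rownames(m)))
  expect_error(supervised_cluster(m, groups, alpha = 1e-12),
               "no assay")
})

test_that("a planted two-group signature is found by supervision among noise", {
  set.seed(31)
  groups <- setNames(rep(c("a", "b"), each = 5), sprintf("s%02d", 1:10))
  noise <- matrix(rnorm(200 * 10, 0, 1), 200)
  sig <- matrix(rnorm(5 * 10, 0, 0.2), 5) +
    outer(rep(2, 5), ifelse(groups == "a", 0, 1))
  m <- rbind(sig, noise)
  dimnames(m) <- list(sprintf("g%03d", 1:205), names(groups))
  hs <- supervised_cluster(m, groups, alpha = 0.001)
  expect_true(all(topology_checks(hs, groups, k = 2)$monophyly))
})

test_that("monophyly and subtree extraction behave on a known tree", {
  m <- matrix(c(0, 0.1, 0.2, 5, 5.1, 20), 1, 6,
              dimnames = list("g", sprintf("s%d", 1:6)))
  h <- hierarchical_cluster(m)
  expect_true(is_monophyletic(h, c("s1", "s2", "s3")))
  expect_true(is_monophyletic(h, c("s4", "s5")))
  expect_false(is_monophyletic(h, c("s1", "s4")))
  expect_true(is_monophyletic(h, "s6"))          # single leaf is trivially so
  expect_setequal(smallest_subtree(h, c("s1", "s4")),
                  c("s1", "s2", "s3", "s4", "s5"))
  expect_error(smallest_subtree(h, "nope"), "not in the tree")
})

test_that("topology report: perfect separation gives monophyly and ARI 1", {
  m <- matrix(c(rnorm(10, 0, 0.05), rnorm(10, 5, 0.05)), 2,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:10)))
  groups <- setNames(rep(c("lo", "hi"), each = 5)[order(c(1:5 * 2 - 1, 1:5 * 2))],
                     colnames(m))
  groups <- setNames(rep(c("lo", "hi"), 5), colnames(m))
  m[, groups == "hi"] <- m[, groups == "hi"] + 50
  h <- hierarchical_cluster(m)
  rep_ <- topology_checks(h, groups, k = 2)
  expect_true(all(rep_$monophyly))
  expect_true(all(rep_$disjoint))
  expect_equal(rep_$ari, 1)
})

test_that("ARI is 1 only for identical partitions and near 0 for random ones", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- c("x", "y", "z")[a]
  expect_equal(adjusted_rand_index(a, relab), 1)
  set.seed(40)
  aris <- replicate(200, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(aris)), 0.05)
  expect_true(all(aris >= -1 & aris <= 1))
})

test_that("Newick export round-trips through ape", {
  m <- matrix(c(0, 1, 5, 9), 1, 4,
              dimnames = list("g", c("a", "b", "c", "d")))
  h <- hierarchical_cluster(m)
  nwk <- as_newick(h)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c", "d"))
  f <- withr::local_tempfile(fileext = ".nwk")
  as_newick(h, f)
  expect_true(file.exists(f))
})

test_that("PCA scores: variance conservation, centering and sign policy", {
  set.seed(27)
  m <- matrix(rnorm(6 * 9), 6, 9,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:9)))
  pc <- pca_scores(m)
  expect_equal(sum(pc$explained_variance), 1)
  expect_true(pc$explained_variance[1] >= pc$explained_variance[2])
  expect_true(all(abs(colMeans(pc$scores)) < 1e-10))
  for (j in seq_len(ncol(pc$loadings)))
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  # variance confined to one direction
  m1 <- matrix(0, 3, 5, dimnames = list(sprintf("g%d", 1:3),
                                        sprintf("s%d", 1:5)))
  m1["g2", ] <- 1:5
  pc1 <- pca_scores(m1)
  expect_equal(pc1$explained_variance[1], 1)
  expect_error(pca_scores(m1 * 0), "constant")
})

test_that("group silhouette in score space separates a planted design", {
  set.seed(3)
  groups <- setNames(rep(c("a", "b", "c"), each = 4), sprintf("s%d", 1:12))
  centers <- cbind(a = c(5, 0, 0), b = c(0, 5, 0), c = c(0, 0, 5))
  m <- matrix(rnorm(36, 0, 0.3), 3) + centers[, rep(1:3, each = 4)]
  m <- rbind(m, matrix(rnorm(5 * 12, 0, 0.3), 5))
  dimnames(m) <- list(sprintf("g%d", 1:8), names(groups))
  sil <- score_silhouette(pca_scores(m), groups)
  expect_gt(sil, 0.5)
})
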