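toy_array <- function(values, neg = NULL) {
  raw <- rbind(values, neg)
  intensity_array(raw, probe_class = setNames(
    rep(c("target", "negative_control"), c(nrow(values), NROW(neg))),
    rownames(raw)))
}

test_that("median normalization brings every array's median to 1", {
  raw <- matrix(c(2, 4, 6), 3, 1, dimnames = list(c("p1", "p2", "p3"), "A1"))
  ia <- median_normalize_array(intensity_array(raw))
  expect_equal(unname(ia$normalized[, 1]), c(0.5, 1, 1.5))
  # already median-1 arrays are unchanged; property holds generally
  set.seed(4)
  raw2 <- matrix(rlnorm(300, 0, 1), 100, 3,
                 dimnames = list(sprintf("p%d", 1:100), sprintf("A%d", 1:3)))
  ia2 <- median_normalize_array(intensity_array(raw2))
  expect_true(all(abs(apply(ia2$normalized, 2, median) - 1) < 1e-9))
  ia3 <- median_normalize_array(intensity_array(ia2$normalized))
  expect_equal(ia3$normalized, ia2$normalized)
})

test_that("detection threshold is mean + k*SD of negative controls", {
  set.seed(8)
  negs <- matrix(0.1, 100, 1, dimnames = list(sprintf("n%d", 1:100), "A1"))
  tg <- matrix(c(1, 2), 2, 1, dimnames = list(c("p1", "p2"), "A1"))
  ia <- toy_array(tg, negs)
  ia$normalized <- ia$raw          # use intensities as-is for the check
  ia <- detection_threshold(ia)
  expect_equal(unname(ia$threshold), 0.1)       # SD = 0 -> threshold = mean
  # worked value: mean 0.1, SD 0.02, k = 3 -> 0.16
  negs2 <- matrix(rep(c(0.08, 0.12), 50), 100, 1,
                  dimnames = list(sprintf("n%d", 1:100), "A1"))
  sdv <- sd(negs2[, 1])
  ia2 <- toy_array(tg, negs2)
  ia2$normalized <- ia2$raw
  ia2 <- detection_threshold(ia2)
  expect_equal(unname(ia2$threshold), 0.1 + 3 * sdv)
  # boundary: a probe exactly at threshold is not absent
  tg3 <- matrix(c(0.1, 0.0999, 0.13), 3, 1,
                dimnames = list(c("at", "below", "margin"), "A1"))
  ia3 <- toy_array(tg3, negs)
  ia3$normalized <- ia3$raw
  ia3 <- detection_threshold(ia3)
  expect_equal(unname(ia3$calls[c("at", "below", "margin"), 1]),
               c("marginal", "absent", "present"))
})

test_that("fold-change selection applies all three criteria", {
  # gene means 2 vs 1 (present) retained; FC 1.9 excluded; absent excluded
  tg <- matrix(c(2.0, 1.9, 3.0,
                 1.0, 1.0, 3.0), 3, 2,
               dimnames = list(c("hit", "weak", "flat"), c("A1", "B1")))
  negs <- matrix(0.05, 100, 2,
                 dimnames = list(sprintf("n%d", 1:100), c("A1", "B1")))
  ia <- toy_array(tg, negs)
  ia$normalized <- ia$raw
  ia <- detection_threshold(ia)
  sel <- select_differential_genes(ia, "A1", "B1")
  expect_identical(sel$retained, "hit")
  st <- setNames(sel$stats$avg_fold_change, sel$stats$assay)
  expect_equal(unname(st["hit"]), 2)
  expect_equal(unname(st["weak"]), 1.9)
  # absent in all samples of both groups excludes regardless of FC
  tg2 <- rbind(tg, dead = c(0.04, 0.01))   # FC 4 but below threshold
  ia2 <- toy_array(tg2, negs)
  ia2$normalized <- ia2$raw
  ia2 <- detection_threshold(ia2)
  sel2 <- select_differential_genes(ia2, "A1", "B1")
  expect_false("dead" %in% sel2$retained)
})

test_that("selection is symmetric in group order and monotone in thresholds", {
  sim <- simulate_high_density(design_high_density(seed = 33))
  ia <- detection_threshold(median_normalize_array(sim$ia))
  ab <- select_differential_genes(ia, sim$group_a, sim$group_b)
  ba <- select_differential_genes(ia, sim$group_b, sim$group_a)
  expect_setequal(ab$retained, ba$retained)
  stricter_fc <- select_differential_genes(ia, sim$group_a, sim$group_b,
                                           fc_threshold = 3)
  stricter_amp <- select_differential_genes(ia, sim$group_a, sim$group_b,
                                            amplitude = 2)
  expect_true(all(stricter_fc$retained %in% ab$retained))
  expect_true(all(stricter_amp$retained %in% ab$retained))
  strict_all <- select_differential_genes(ia, sim$group_a, sim$group_b,
                                          call_rule = "all_samples")
  expect_true(all(strict_all$retained %in% ab$retained))
})

test_that("planted scale factors are undone by median normalization", {
  sim <- simulate_high_density(design_high_density(seed = 5, noise_sdlog = 0,
                                                   scale_sdlog = 0.5))
  ia <- median_normalize_array(sim$ia)
  # same-group target probes agree after normalization despite scale factors
  a <- ia$normalized[ia$probe_class == "target", sim$group_a]
  expect_lt(max(abs(a - a[, 1])), 1e-9)
})

test_that("no-effect, zero-noise arrays retain nothing", {
  d <- design_high_density(seed = 2, n_strong = 0, n_weak = 0,
                           noise_sdlog = 0)
  sim <- simulate_high_density(d)
  ia <- detection_threshold(median_normalize_array(sim$ia))
  sel <- select_differential_genes(ia, sim$group_a, sim$group_b)
  expect_length(sel$retained, 0)
})

test_that("candidate lists intersect with card availability in order", {
  expect_identical(intersect_available_assays(c("c", "a", "b"), c("b", "c")),
                   c("c", "b"))
})
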