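make_ct <- function(values, card) {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(sprintf("g%d", seq_len(nrow(values))),
                             sprintf("s%d", seq_len(ncol(values))))
  ct_matrix(values, card = card)
}

test_that("Ct cut-off discards late values and only late values", {
  m <- matrix(c(36.2, 34.9, 36.5, 20), 4, 1,
              dimnames = list(sprintf("g%d", 1:4), "s1"))
  ct <- make_ct(m, c(s1 = "c1"))
  cut35 <- apply_ct_cutoff(ct, 35)
  expect_true(is.na(cut35$values["g1", "s1"]))
  expect_equal(cut35$values["g2", "s1"], 34.9)
  cut37 <- apply_ct_cutoff(ct, 37)
  expect_equal(cut37$values["g3", "s1"], 36.5)
  # original untouched
  expect_equal(ct$values["g1", "s1"], 36.2)
  expect_error(apply_ct_cutoff(ct, -1), "cutoff")
})

test_that("raising the cutoff never decreases the number of present cells", {
  for (seed in 1:20) {
    ct <- random_ct(15, 3, 3, nondetect_frac = 0.1, seed = seed)
    counts <- vapply(c(25, 30, 33, 36, 50),
                     function(cf) n_detected(apply_ct_cutoff(ct, cf)),
                     numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("card-median correction hits the worked two-card example", {
  m <- matrix(c(20, 22, 24, 21, 23, 25), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ct <- make_ct(m, c(s1 = "cA", s2 = "cB"))
  res <- card_median_correction(ct)
  expect_equal(res$target, 22.5)
  expect_equal(res$factors$correction[res$factors$card == "cA"], 0.5)
  expect_equal(res$factors$correction[res$factors$card == "cB"], -0.5)
  expect_equal(unname(res$ct$values[, "s1"]), c(20.5, 22.5, 24.5))
  meds <- tapply(seq_len(2), res$ct$card, function(ix)
    median(res$ct$values[, ix]))
  expect_true(all(abs(unlist(meds) - 22.5) < 1e-9))
  # already-on-target card is untouched
  res2 <- card_median_correction(ct, target = 22)
  expect_equal(res2$ct$values[, "s1"], m[, "s1"] + 0)
})

test_that("delta-Ct centres on the card median or a reference gene", {
  m <- matrix(c(24, 22.5, 21), 3, 1,
              dimnames = list(c("g1", "med", "g3"), "s1"))
  ct <- make_ct(m, c(s1 = "c1"))
  d <- delta_ct(ct, "card_median")
  expect_equal(d$dct["g1", "s1"], 1.5)
  expect_equal(d$dct["med", "s1"], 0)
  dr <- delta_ct(ct, "med")
  expect_equal(dr$dct["med", "s1"], 0)
  expect_equal(dr$dct["g1", "s1"], 1.5)
  # reference non-detect masks the sample, with a warning
  m2 <- cbind(m, s2 = c(25, NA, 22))
  ct2 <- make_ct(m2, c(s1 = "c1", s2 = "c1"))
  expect_warning(d2 <- delta_ct(ct2, "med"), "masked")
  expect_true(all(is.na(d2$dct[, "s2"])))
})

test_that("correction-then-delta-Ct commutes with direct per-card delta-Ct", {
  for (seed in 1:10) {
    ct <- random_ct(20, 4, 3, nondetect_frac = 0.1, seed = seed)
    direct <- delta_ct(ct, "card_median")$dct
    corrected <- card_median_correction(ct)
    via <- corrected$ct$values - corrected$target
    expect_equal(via, direct, tolerance = 1e-9)
  }
})

test_that("delta-delta-Ct reproduces the {1,2,3} worked example", {
  d <- dct_matrix(matrix(c(1, 2, 3), 1, 3,
                         dimnames = list("g1", c("s1", "s2", "s3"))),
                  centering = "card_median")
  rq <- delta_delta_ct(d)
  expect_equal(unname(rq$rq["g1", ]), c(2, 1, 0.5))
  expect_equal(rq$reference_mode, "virtual_housekeeping")
  # constant assay gives RQ 1 everywhere
  dc <- dct_matrix(matrix(2, 1, 3, dimnames = list("g1", c("a", "b", "c"))),
                   centering = "card_median")
  expect_true(all(delta_delta_ct(dc)$rq == 1))
})

test_that("a designated calibrator sample gets RQ 1 for every assay", {
  set.seed(3)
  d <- dct_matrix(matrix(rnorm(40), 8, 5,
                         dimnames = list(sprintf("g%d", 1:8),
                                         sprintf("s%d", 1:5))),
                  centering = "card_median")
  rq <- delta_delta_ct(d, reference = "s2")
  expect_equal(unname(rq$rq[, "s2"]), rep(1, 8))
  expect_match(rq$reference_mode, "baseline_sample")
})

test_that("RQ positivity and the geometric-mean-1 law hold over random inputs", {
  for (seed in 1:200) {
    ct <- random_ct(n_assays = 12, n_cards = sample(2:4, 1),
                    samples_per_card = 3, nondetect_frac = 0.1, seed = seed)
    rq <- suppressWarnings(delta_delta_ct(delta_ct(ct, "card_median")))
    vals <- rq$rq[!is.na(rq$rq)]
    expect_true(all(vals > 0))
    gm <- apply(rq$rq, 1, function(v) geo_mean(v[!is.na(v)]))
    expect_true(all(abs(gm - 1) < 1e-9))
  }
})

test_that("Ntarget follows 2^(Ct_ref - Ct_target)", {
  m <- matrix(c(20, 18, 23, 20, 20, 20), 3, 2,
              dimnames = list(c("ETV6", "t1", "t2"), c("s1", "s2")))
  ct <- make_ct(m, c(s1 = "c1", s2 = "c1"))
  rq <- ntarget_reference_gene(ct, reference_assay = "ETV6")
  expect_equal(rq$rq["t1", "s1"], 4)
  expect_equal(rq$rq["t2", "s1"], 0.125)
  expect_equal(rq$rq["t1", "s2"], 1)
  expect_equal(rq$reference_mode, "reference_gene(ETV6)")
  # non-detect reference masks the cell
  m[1, 2] <- NA
  ct2 <- make_ct(m, c(s1 = "c1", s2 = "c1"))
  rq2 <- ntarget_reference_gene(ct2, reference_assay = "ETV6")
  expect_true(all(is.na(rq2$rq[, "s2"])))
})

test_that("tumour correcting factors equalize the reference across tumours", {
  m <- matrix(c(24, 30, 26, 31), 2, 2,
              dimnames = list(c("ETV6", "g1"), c("t1", "t2")))
  ct <- make_ct(m, c(t1 = "cA", t2 = "cB"))
  res <- tumor_correcting_factors(ct, "ETV6")
  expect_equal(res$grand_mean, 25)
  expect_equal(res$factors$F, c(1, -1))
  expect_equal(unname(res$ct$values["ETV6", ]), c(25, 25))
  expect_equal(sd(res$ct$values["ETV6", ]), 0)
  # single tumour: F = 0, values unchanged
  ct1 <- make_ct(m[, 1, drop = FALSE], c(t1 = "cA"))
  res1 <- tumor_correcting_factors(ct1, "ETV6")
  expect_equal(res1$factors$F, 0)
  expect_equal(res1$ct$values, ct1$values)
  # undetected reference is a hard error naming the tumour
  m[1, 2] <- NA
  expect_error(tumor_correcting_factors(make_ct(m, c(t1 = "cA", t2 = "cB")),
                                        "ETV6"), "t2")
})

test_that("baseline-group folds are geometric-mean ratios, scale invariant", {
  m <- matrix(c(4, 1, 4), 1, 3, dimnames = list("g1", c("x", "b1", "b2")))
  rq <- rq_matrix(m)
  groups <- c(x = "mut", b1 = "WT", b2 = "WT")
  fold <- fold_vs_baseline_group(rq, groups, "WT")
  expect_equal(fold$rq["g1", "x"], 2)          # 4 / geomean(1, 4)
  expect_equal(geo_mean(fold$rq["g1", c("b1", "b2")]), 1)
  doubled <- fold_vs_baseline_group(rq_matrix(2 * m), groups, "WT")
  expect_equal(doubled$rq, fold$rq)
  # all-equal baseline, member of baseline: fold 1
  m2 <- matrix(c(3, 3), 1, 2, dimnames = list("g1", c("b1", "b2")))
  f2 <- fold_vs_baseline_group(rq_matrix(m2), c(b1 = "WT", b2 = "WT"), "WT")
  expect_equal(unname(f2$rq[1, ]), c(1, 1))
})
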