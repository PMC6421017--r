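test_that("confusion counts match exhaustive enumeration", {
  truth <- matrix(FALSE, 3, 3); truth[1, ] <- TRUE
  pred <- matrix(FALSE, 3, 3); pred[, 1] <- TRUE
  cc <- confusion(pred, truth)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1, 2, 2, 4))

  set.seed(11)
  for (rep in 1:20) {
    p <- matrix(runif(64) > 0.5, 8, 8)
    t <- matrix(runif(64) > 0.5, 8, 8)
    cc <- confusion(p, t)
    # brute force pixel by pixel
    tp <- fp <- tn <- fn <- 0
    for (i in 1:8) for (j in 1:8) {
      if (p[i, j] && t[i, j]) tp <- tp + 1
      else if (p[i, j] && !t[i, j]) fp <- fp + 1
      else if (!p[i, j] && t[i, j]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(tp, fp, tn, fn))
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 64)
  }

  expect_error(confusion(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shape")
})

test_that("metrics reproduce published example rows", {
  m <- compute_metrics(confusion_counts(556, 5, 14795, 37))
  expect_equal(m[["dice"]], 0.9636, tolerance = 1e-4)
  expect_equal(m[["sensitivity"]], 0.9376, tolerance = 1e-4)

  m2 <- compute_metrics(confusion_counts(1160, 287, 18241, 0))
  expect_equal(m2[["accuracy"]], 0.9854, tolerance = 1e-4)
  expect_equal(m2[["sensitivity"]], 1)
})

test_that("metric identities hold", {
  m <- compute_metrics(confusion_counts(100, 0, 500, 0))
  expect_true(all(unclass(m) == 1))

  set.seed(3)
  for (rep in 1:25) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    m <- compute_metrics(cc)
    if (!is.na(m[["dice"]]) && !is.na(m[["jaccard"]])) {
      expect_equal(m[["dice"]], 2 * m[["jaccard"]] / (1 + m[["jaccard"]]),
                   tolerance = 1e-12)
    }
    if (!is.na(m[["sensitivity"]]))
      expect_equal(m[["sensitivity"]] == 1, cc$fn == 0)
    if (!is.na(m[["specificity"]]))
      expect_equal(m[["specificity"]] == 1, cc$fp == 0)
    ok <- unclass(m)[!is.na(unclass(m))]
    expect_true(all(ok >= 0 & ok <= 1))
  }
})

test_that("undefined metrics are NA, not coerced", {
  m <- compute_metrics(confusion_counts(0, 0, 10, 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_true(is.na(m[["dice"]]))
  expect_true(is.na(m[["jaccard"]]))
  expect_false(is.na(m[["specificity"]]))
})

test_that("reduced rates follow the clamped area-normalized definition", {
  base <- confusion_counts(592, 285, 14515, 1)
  th <- confusion_counts(556, 5, 14795, 37)
  rr <- reduced_rates(base, th)
  expect_equal(unname(rr["reduced_fp_pct"]), 1.89, tolerance = 0.005)
  expect_equal(unname(rr["reduced_fn_pct"]), 0)    # thermal FN grew: clamped

  expect_equal(unname(reduced_rates(base, base)), c(0, 0))
  worse <- confusion_counts(500, 400, 14400, 93)
  expect_equal(unname(reduced_rates(base, worse)), c(0, 0))
  expect_error(reduced_rates(base, confusion_counts(1, 1, 1, 1)),
               "input error")
})

test_that("cohort summaries are column means with input checks", {
  expect_equal(unname(cohort_summary(rbind(c(1, 2)))), c(1, 2))
  expect_equal(unname(cohort_summary(list(c(0, 0), c(0, 0)))), c(0, 0))
  expect_equal(unname(cohort_summary(rbind(c(1, 3), c(3, 5)))), c(2, 4))
  expect_error(cohort_summary(matrix(numeric(0), 0, 2)), "empty")
})

test_that("bundled reference tables are complete and self-consistent", {
  df <- reference_segmentations("all")
  expect_equal(nrow(df), 48)
  expect_true(all(df$tp + df$fp + df$tn + df$fn > 10000))
  rr <- reference_reduced_rates()
  expect_equal(nrow(rr), 16)
  expect_equal(nrow(reference_segmentations("phantom")), 12)
})
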