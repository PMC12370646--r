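test_that("per-class metrics implement the undefined-class conventions", {
  # diagonal: everything 1
  cm <- diag(c(5L, 3L, 2L))
  pcm <- per_class_metrics(cm)
  expect_true(all(pcm$precision == 1 & pcm$recall == 1 & pcm$f1 == 1))
  # published example: precision 0.855, recall 0.803 -> F1 0.828
  f1 <- 2 * 0.855 * 0.803 / (0.855 + 0.803)
  expect_equal(round(f1, 3), 0.828)
  # class present but never predicted: precision NA, recall 0, F1 NA
  cm2 <- matrix(c(4L, 1L, 0L, 0L), 2, 2)
  pcm2 <- per_class_metrics(cm2)
  expect_true(is.na(pcm2$precision[2]))
  expect_equal(pcm2$recall[2], 0)
  expect_true(is.na(pcm2$f1[2]))
  # precision = recall = 0 (sum zero): F1 undefined
  cm3 <- matrix(c(3L, 1L, 0L, 0L, 0L, 1L, 1L, 1L, 0L), 3, 3, byrow = TRUE)
  pcm3 <- per_class_metrics(cm3)
  expect_equal(pcm3$precision[3], 0)
  expect_equal(pcm3$recall[3], 0)
  expect_true(is.na(pcm3$f1[3]))
})

test_that("weighted F1 keeps undefined-class support in the denominator", {
  cmx <- data.frame(class = 0:2, precision = NA, recall = NA,
                    f1 = c(0.909, NA, 0.737), support = c(32L, 5L, 8L))
  expect_equal(round(weighted_f1(cmx), 3), 0.777)
  one <- data.frame(class = 0, precision = 1, recall = 1, f1 = 0.6,
                    support = 10L)
  expect_equal(weighted_f1(one), 0.6)
})

test_that("macro F1 averages only defined classes", {
  cmx <- data.frame(f1 = c(0.828, 0.622, 0.429), support = c(117L, 56L, 7L))
  expect_equal(round(macro_f1(cmx), 3), 0.626)
  cmx2 <- data.frame(f1 = c(0.909, NA, 0.737), support = c(32L, 5L, 8L))
  expect_equal(round(macro_f1(cmx2), 3), 0.823)
  expect_error(macro_f1(data.frame(f1 = c(NA, NA), support = c(1L, 1L))),
               "undefined")
  # weighted and macro coincide for equal supports and defined F1s
  cmx3 <- data.frame(f1 = c(0.4, 0.8), support = c(10L, 10L))
  expect_equal(weighted_f1(cmx3), macro_f1(cmx3))
})

test_that("accuracy within k levels follows the banded-count arithmetic", {
  cm <- diag(c(4L, 4L, 2L))
  expect_equal(acc_within(cm, 0), 100)
  expect_equal(acc_within(cm, 1), 100)
  cm2 <- matrix(c(1L, 1L, 1L, 1L), 2, 2)
  expect_equal(acc_within(cm2, 0), 50)
  expect_equal(acc_within(cm2, 1), 100)
  set.seed(3)
  for (rep in 1:10) {
    cmr <- matrix(sample(0:5, 16, TRUE), 4, 4)
    if (sum(cmr) == 0) next
    expect_lte(acc_within(cmr, 0), acc_within(cmr, 1))
  }
})

test_that("quadratic weighted kappa has the expected fixed points", {
  expect_equal(weighted_kappa(diag(c(10L, 5L, 3L))), 1)
  cm <- matrix(c(2L, 1L, 0L, 1L), 2, 2, byrow = TRUE)
  expect_equal(weighted_kappa(cm), 0.5) # hand-computed 2x2 case
  # invariant to scaling the matrix by a positive integer
  expect_equal(weighted_kappa(cm * 7L), weighted_kappa(cm))
  # independent uniform marginals: kappa ~ 0
  set.seed(12)
  n <- 1e5
  a <- sample(0:3, n, TRUE)
  b <- sample(0:3, n, TRUE)
  expect_lt(abs(weighted_kappa(confusion_matrix(a, b, 4L))), 0.02)
  # degenerate marginals: undefined
  expect_true(is.na(weighted_kappa(matrix(c(5L, 0L, 0L, 0L), 2, 2))))
  expect_equal(kappa_band(0.53), "moderate agreement")
  expect_equal(kappa_band(0.85), "almost perfect agreement")
})

test_that("regression metrics follow the printed formulas", {
  r <- regression_metrics(c(1, 2), c(2, 4))
  expect_equal(r$mae, 1.5)
  expect_equal(r$rmse, sqrt(2.5))
  y <- c(3, 1, 4, 1, 5)
  r2 <- regression_metrics(y, y)
  expect_equal(r2$mae, 0)
  expect_equal(r2$rmse, 0)
  expect_equal(r2$spearman_r, 1)
  r3 <- regression_metrics(1:6, 6:1)
  expect_equal(r3$spearman_r, -1)
  expect_error(regression_metrics(1, 1), "at least 2")
  expect_equal(correlation_band(0.798), "strong correlation")
})

test_that("table reconstruction reproduces printed aggregates", {
  # arising-from-chair LOOCV block
  rec <- reconstruct_from_table(precision = c(0.855, 0.587, 0.429),
                                recall = c(0.803, 0.661, 0.429),
                                support = c(117L, 56L, 7L))
  expect_equal(round(rec$weighted_f1, 3), 0.748)
  expect_equal(round(rec$macro_f1, 3), 0.626)
  expect_equal(round(rec$acc_exact, 1), 74.4)
  # postural-stability test block (two undefined classes)
  rec2 <- reconstruct_from_table(
    precision = c(0.562, 0.273, 0, 0.462, 0),
    recall = c(0.6, 0.3, 0, 0.353, 0),
    support = c(15L, 10L, 2L, 17L, 1L))
  expect_equal(round(rec2$macro_f1, 3), 0.422)
  expect_equal(round(rec2$weighted_f1, 3), 0.408)
  expect_equal(round(rec2$acc_exact, 1), 40.0)
  # perfect table
  rec3 <- reconstruct_from_table(c(1, 1), c(1, 1), c(9L, 3L))
  expect_equal(rec3$acc_exact, 100)
  # printed rounding inconsistency warning
  expect_warning(reconstruct_from_table(0.5, 0.5, 5L), "rounding")
})

test_that("feature-score correlations have the expected signs", {
  scores <- rep(0:4, each = 8)
  fsc <- feature_score_correlation(as.numeric(scores), scores)
  expect_equal(fsc$r, 1)
  expect_true(is.na(feature_score_correlation(rep(1, 40), scores)$r))
  # generator monotonicity: swing RoM anti-correlates with gait severity,
  # turn steps correlate with freezing severity
  mono_g <- single_theta_features("gait")
  sc_g <- round(4 * mono_g$theta) # noise-free scores
  fsc_g <- feature_score_correlation(
    mono_g$features[, "Shank—Swing RoM—mean (max)"], sc_g)
  expect_lt(fsc_g$r, 0)
  expect_lt(fsc_g$p, 0.001)
  mono_f <- single_theta_features("fog")
  fsc_f <- feature_score_correlation(
    mono_f$features[, "180° Turn—Steps—mean"], round(4 * mono_f$theta))
  expect_gt(fsc_f$r, 0)
  expect_lt(fsc_f$p, 0.001)
})

test_that("item reports bundle the metrics consistently", {
  cm <- matrix(c(20L, 3L, 0L, 4L, 10L, 2L, 1L, 2L, 6L), 3, 3, byrow = TRUE)
  rep <- item_report(cm)
  expect_lte(rep$acc_exact, rep$acc_within1)
  expect_lte(rep$acc_within1, 100)
  expect_gte(rep$acc_exact, 0)
  expect_lte(rep$kappa_w, 1)
  expect_equal(rep$n, sum(cm))
  expect_equal(rep$weighted_f1, weighted_f1(per_class_metrics(cm)))
})
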