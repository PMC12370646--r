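counts_to_scores <- function(counts) rep(0:4, counts)

test_that("sparse score levels merge downward on original training counts", {
  mm <- merge_levels(counts_to_scores(c(150, 60, 20, 4, 2)))
  expect_equal(mm$M, 3L)
  expect_equal(mm$labels, c("0", "1", "2/3/4"))
  expect_equal(mm$map, c(0L, 1L, 2L, 2L, 2L))
  # freezing-of-gait-like counts: 3-level map 0, 1, 2/3/4
  mm2 <- merge_levels(counts_to_scores(c(146, 6, 20, 5, 3)))
  expect_equal(mm2$labels, c("0", "1", "2/3/4"))
  # posture-like counts: 4-level map 0, 1, 2, 3/4
  mm3 <- merge_levels(counts_to_scores(c(49, 80, 33, 15, 3)))
  expect_equal(mm3$M, 4L)
  expect_equal(mm3$labels, c("0", "1", "2", "3/4"))
  # gait-like counts (no score-4 participants): 0, 1, 2/3
  mm4 <- merge_levels(rep(0:3, c(13, 70, 92, 5)))
  expect_equal(mm4$labels, c("0", "1", "2/3"))
  # an under-populated bottom level merges upward
  mm5 <- merge_levels(rep(0:2, c(3, 40, 30)))
  expect_equal(mm5$labels, c("0/1", "2"))
  # all mass in one level is not modelable
  expect_error(merge_levels(rep(2L, 50)), "single-class")
})

test_that("merge maps are monotone, surjective, and apply verbatim to test data", {
  set.seed(2)
  for (rep in 1:20) {
    counts <- stats::rmultinom(1, 180, c(0.4, 0.3, 0.15, 0.1, 0.05))[, 1]
    if (max(counts) == 180) next
    scores <- counts_to_scores(counts)
    mm <- tryCatch(merge_levels(scores), error = function(e) NULL)
    if (is.null(mm)) next
    expect_true(all(diff(mm$map) >= 0)) # monotone non-decreasing
    expect_equal(sort(unique(mm$map)), 0:(mm$M - 1L)) # surjective
    test_scores <- sample(unique(scores), 30, replace = TRUE)
    expect_true(all(apply_merge(test_scores, mm) %in% 0:(mm$M - 1L)))
    expect_identical(apply_merge(test_scores, mm), mm$map[test_scores + 1L])
  }
})

test_that("cohort splits are balanced, level-complete and deterministic", {
  labels <- label_table(225, seed = 11)
  sp <- split_cohort(labels, seed = 5)
  expect_length(sp$train_ids, 180L)
  expect_length(sp$test_ids, 45L)
  expect_true(all(sp$balance_p > 0.05))
  for (it in item_names()) {
    tr_lv <- unique(labels[[it]][labels$participant %in% sp$train_ids])
    expect_true(all(unique(labels[[it]]) %in% tr_lv))
  }
  sp2 <- split_cohort(labels, seed = 5)
  expect_identical(sp$train_ids, sp2$train_ids)
  # a singleton level is forced into training
  labels2 <- label_table(60, seed = 3)
  labels2$item_3_9[1] <- 4L
  labels2$item_3_9[-1] <- pmin(labels2$item_3_9[-1], 3L)
  sp3 <- split_cohort(labels2, seed = 9)
  expect_true(labels2$participant[1] %in% sp3$train_ids)
})

test_that("SMOTE balances classes without leaving the class hull", {
  set.seed(1)
  X <- matrix(stats::rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c(0L, 1L, 2L), c(40, 15, 5))
  sm <- smote_balance(X, y, k = 5, seed = 3)
  expect_equal(as.integer(table(sm$y)), rep(40L, 3))
  expect_identical(smote_balance(X, y, k = 5, seed = 3)$X, sm$X)
  # synthetic rows are convex combinations within their class bounds
  for (cl in 1:2) {
    orig <- X[y == cl, , drop = FALSE]
    syn <- sm$X[sm$synthetic & sm$y == cl, , drop = FALSE]
    expect_true(all(syn >= matrix(apply(orig, 2, min), nrow(syn), 4,
                                  byrow = TRUE) - 1e-12))
    expect_true(all(syn <= matrix(apply(orig, 2, max), nrow(syn), 4,
                                  byrow = TRUE) + 1e-12))
  }
  # singleton class duplicates; tiny classes shrink k
  y2 <- rep(c(0L, 1L), c(10, 1))
  sm2 <- smote_balance(X[1:11, ], y2, k = 5, seed = 1)
  expect_equal(sum(sm2$y == 1L), 10L)
  syn1 <- sm2$X[sm2$synthetic & sm2$y == 1L, , drop = FALSE]
  expect_true(all(apply(syn1, 1, function(r) all(r == X[11, ]))))
})

test_that("Gain ranking finds a planted signal feature first", {
  set.seed(7)
  n <- 200
  X <- matrix(stats::rnorm(n * 30), n, 30,
              dimnames = list(NULL, sprintf("noise%02d", 1:30)))
  colnames(X)[17] <- "signal"
  y <- as.integer(X[, 17] > 0.2)
  rk <- rank_features_by_gain(X, y, seed = 1)
  expect_equal(rk$feature[1], "signal")
  expect_true(all(rk$gain >= 0))
  # duplicate columns stay present with deterministic name tie-break
  X2 <- cbind(X, X[, 17, drop = FALSE])
  colnames(X2)[31] <- "signal2"
  rk2 <- rank_features_by_gain(X2, y, seed = 1)
  expect_true(all(c("signal", "signal2") %in% rk2$feature))
  zero <- rk2[rk2$gain == 0, "feature"]
  expect_identical(zero, sort(zero, method = "radix"))
})

test_that("LOOCV never exposes the left-out sample to SMOTE", {
  set.seed(5)
  n <- 24
  X <- matrix(stats::rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c(0L, 1L), each = n / 2)
  seen <- list()
  cv <- loocv_evaluate(X, y, paste0("f", 1:8), k_grid = 5,
                       grids = list(gbt = compact_grids()$gbt[1, ],
                                    svm = NULL),
                       seed = 2, nrounds = 3,
                       fold_callback = function(i, tr, smote_idx) {
                         seen[[length(seen) + 1]] <<- list(i = i, tr = tr,
                                                           sm = smote_idx)
                       })
  expect_length(seen, n)
  for (s in seen) {
    expect_false(s$i %in% s$tr)
    expect_false(s$i %in% s$tr[s$sm])
    expect_length(s$tr, n - 1L)
  }
})

test_that("a separable problem reaches 100% LOOCV accuracy and the grid is exhaustive", {
  set.seed(8)
  n <- 20
  X <- matrix(stats::rnorm(n * 52), n, 52,
              dimnames = list(NULL, sprintf("f%02d", 1:52)))
  # discrete signal values, so every left-out value also occurs in training
  X[, 1] <- sample(rep(c(-2, -1, 1, 2), each = 5))
  y <- as.integer(X[, 1] > 0)
  rk <- paste0("f", sprintf("%02d", 1:52))
  cv <- loocv_evaluate(X, y, rk, k_grid = seq(5, 50, by = 5),
                       grids = list(gbt = default_grids()$gbt, svm = NULL),
                       seed = 1, nrounds = 10)
  # 10 feature counts x 24 hyperparameter combinations = 240 configurations
  expect_equal(nrow(cv$results), 240L)
  expect_equal(max(cv$results$acc0), 100)
})

test_that("configuration selection follows the declared tie-breaks", {
  fake <- structure(list(
    results = data.frame(config = 1:4,
                         algorithm = c("svm", "gbt", "gbt", "gbt"),
                         K = c(10L, 30L, 10L, 20L),
                         weighted_f1 = c(0.9, 0.9, 0.9, 0.85),
                         acc0 = c(80, 80, 80, 90)),
    preds = rep(list(c(0L, 1L, 0L, 1L)), 4),
    configs = list(list(algorithm = "svm", K = 10L),
                   list(algorithm = "gbt", K = 30L),
                   list(algorithm = "gbt", K = 10L),
                   list(algorithm = "gbt", K = 20L)),
    M = 2L, y = c(0L, 1L, 0L, 1L), n_flagged_folds = 0L
  ), class = "loocv_result")
  best <- select_best(fake)
  expect_equal(best$K, 10L) # smaller K wins the weighted-F1 tie
  expect_equal(best$algorithm, "gbt") # gbt before svm at equal K
})

test_that("final refits are deterministic and serialize without drift", {
  set.seed(10)
  n <- 60
  X <- matrix(stats::rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- as.integer(X[, 1] + 0.3 * stats::rnorm(n) > 0)
  best <- list(algorithm = "gbt", K = 10L, eta = 0.1, max_depth = 3L,
               gamma = 0.1, lambda = 3)
  Xnew <- matrix(stats::rnorm(20 * 10), 20, 10,
                 dimnames = list(NULL, paste0("f", 1:10)))
  m1 <- fit_final(X, y, best, seed = 4)
  m2 <- fit_final(X, y, best, seed = 4)
  expect_identical(predict(m1, Xnew), predict(m2, Xnew))
  f <- tempfile(fileext = ".rds")
  save_item_model(m1, f)
  m3 <- load_item_model(f)
  expect_identical(predict(m3, Xnew), predict(m1, Xnew))
  unlink(f)
  # rbf route fits and predicts merged levels
  m4 <- fit_final(X, y, list(algorithm = "svm", gamma = 0.1, cost = 1),
                  seed = 4)
  expect_true(all(predict(m4, Xnew) %in% 0:1))
})

test_that("the LASSO subscale model recovers a planted linear signal", {
  set.seed(6)
  n <- 200
  X <- matrix(stats::rnorm(n * 51), n, 51,
              dimnames = list(NULL, c("f1", sprintf("n%02d", 1:50))))
  y <- 3 * X[, "f1"] + stats::rnorm(n, 0, 0.5)
  sub <- fit_subscale(X, y, seed = 2)
  expect_true("f1" %in% sub$features)
  expect_equal(unname(sub$beta[["f1"]]), 3, tolerance = 0.3)
  expect_lt(length(sub$features), 20L) # most noise features zeroed
  # infinite regularization: all betas zero, intercept = mean(y)
  co <- as.matrix(stats::coef(sub$cvfit, s = max(sub$cvfit$lambda) * 100))
  expect_true(all(co[-1, 1] == 0))
  expect_equal(co[1, 1], mean(y), tolerance = 1e-6)
  expect_error(fit_subscale(X, rep(3, n)), "degenerate")
})

test_that("sensor contributions count features once per contributing group", {
  # 35 features, 10 of them shank-derived -> 28.6%
  feats <- c(rep("Shank—Swing RoM—mean (max)", 10),
             rep("Trunk—Max Sagittal Angular Velocity—mean", 25))
  contrib <- sensor_contribution(feats)
  expect_equal(unname(contrib[["shank"]]), 100 * 10 / 35, tolerance = 1e-6)
  expect_equal(unname(contrib[["chest"]]), 100 * 25 / 35, tolerance = 1e-6)
  expect_equal(sum(contrib), 100) # single-sensor features sum to 100
  # a multi-sensor feature counts once for each group
  both <- sensor_contribution(c("180° Turn—Steps—mean",
                                "Gait Speed—mean"))
  expect_equal(unname(both[["waist"]]), 100)
  expect_equal(unname(both[["shank"]]), 50)
  expect_gt(sum(both), 100)
  expect_error(sensor_contribution("Not A Feature—mean"), "unregistered")
})
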