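#' Balanced train/test split of a cohort
#'
#' Random 80/20 participant splits are redrawn until (a) every observed score
#' level of every item appears in the training set and (b) the sets are
#' demographically matched: Mann-Whitney p > 0.05 for age and disease
#' duration, chi-square p > 0.05 for sex.
#'
#' @param labels cohort label table (`participant`, five item columns, `age`,
#'   `sex`, `pd_duration`).
#' @param train_frac training fraction.
#' @param max_tries maximum redraws before failing with the violated
#'   constraint.
#' @param seed integer seed (the split is deterministic given it).
#' @return list `train_ids`, `test_ids`, `tries`, `balance_p` (named vector).
#' @export
split_cohort <- function(labels, train_frac = 0.8, max_tries = 200, seed = 1L) {
  n <- nrow(labels)
  stopifnot(n >= 10)
  n_train <- round(train_frac * n)
  items <- intersect(item_names(), names(labels))
  with_seed(seed, {
    last_fail <- "none"
    for (try in seq_len(max_tries)) {
      idx <- sample.int(n, n_train)
      ok <- TRUE
      for (it in items) {
        if (!all(unique(labels[[it]]) %in% labels[[it]][idx])) {
          ok <- FALSE
          last_fail <- paste("missing level in training for", it)
          break
        }
      }
      if (ok) {
        p_age <- suppressWarnings(stats::wilcox.test(
          labels$age[idx], labels$age[-idx])$p.value)
        p_dur <- suppressWarnings(stats::wilcox.test(
          labels$pd_duration[idx], labels$pd_duration[-idx])$p.value)
        grp <- factor(seq_len(n) %in% idx, levels = c(TRUE, FALSE))
        p_sex <- if (length(unique(labels$sex)) < 2L) 1 else
          suppressWarnings(stats::chisq.test(table(labels$sex, grp))$p.value)
        if (min(p_age, p_dur, p_sex, na.rm = TRUE) <= 0.05) {
          ok <- FALSE
          last_fail <- "demographic imbalance"
        }
      }
      if (ok) {
        return(list(train_ids = sort(labels$participant[idx]),
                    test_ids = sort(labels$participant[-idx]),
                    tries = try,
                    balance_p = c(age = p_age, pd_duration = p_dur,
                                  sex = p_sex)))
      }
    }
    stop("split_cohort: max_tries exhausted; last failing constraint: ",
         last_fail)
  })
}

#' Merge sparse score levels into an M-level categorical variable
#'
#' A score level whose training-set count is at or below `min_n` is merged
#' into the previous (lower) level, judged on the original per-level counts
#' and cascading downwards, so several adjacent sparse top levels collapse
#' into the highest well-populated level (e.g. counts 150/60/20/4/2 give the
#' 3-level variable 0, 1, 2/3/4). If the lowest resulting group is itself
#' at or below `min_n`, it merges upward. The same map must be applied
#' verbatim to test data.
#'
#' @param train_scores integer scores 0-4 of the training set.
#' @param min_n merge threshold (level merged when count <= `min_n`).
#' @return object of class `merge_map`: `map` (length-5 integer vector,
#'   original score -> merged level), `labels`, `M`.
#' @export
merge_levels <- function(train_scores, min_n = 5) {
  stopifnot(all(train_scores %in% 0:4))
  maxobs <- max(train_scores)
  counts <- tabulate(factor(train_scores, levels = 0:maxobs), maxobs + 1L)
  grp <- integer(maxobs + 1L)
  g <- 0L
  for (l in seq_len(maxobs)) { # levels 1..maxobs; level 0 anchors group 0
    if (counts[l + 1L] > min_n) g <- g + 1L
    grp[l + 1L] <- g
  }
  # an under-populated bottom group merges upward
  if (max(grp) > 0L && sum(counts[grp == 0L]) <= min_n) grp <- pmax(grp - 1L, 0L)
  grp <- match(grp, sort(unique(grp))) - 1L
  M <- max(grp) + 1L
  if (M < 2L) stop("single-class item: all mass in one merged level")
  map <- c(grp, rep(grp[maxobs + 1L], 4L - maxobs)) # unseen top levels clip
  labels <- vapply(0:(M - 1L), function(m)
    paste(which(grp == m) - 1L, collapse = "/"), "")
  structure(list(map = map, labels = labels, M = M), class = "merge_map")
}

#' Apply a merge map to raw 0-4 scores
#'
#' @param scores integer scores 0-4.
#' @param mm a `merge_map`.
#' @return integer merged levels `0..M-1`.
#' @export
apply_merge <- function(scores, mm) {
  stopifnot(inherits(mm, "merge_map"), all(scores %in% 0:4))
  mm$map[scores + 1L]
}

#' SMOTE oversampling to class balance
#'
#' Minority classes are oversampled to the majority count by interpolating
#' between a member and one of its `k` nearest within-class neighbours
#' (`x_new = x_i + u * (x_j - x_i)`, `u ~ U(0,1)`). Distances are computed on
#' per-feature standardized scale; interpolation acts on the raw scale. When
#' a minority class has `m < k + 1` members, `k` drops to `m - 1`; a singleton
#' class is duplicated.
#'
#' @param X numeric matrix (rows = samples).
#' @param y integer class labels.
#' @param k neighbour count.
#' @param seed integer seed.
#' @return list `X`, `y`, `synthetic` (logical marking generated rows).
#' @export
smote_balance <- function(X, y, k = 5, seed = 1L) {
  X <- as.matrix(X)
  tab <- table(y)
  target <- max(tab)
  sds <- apply(X, 2L, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  newX <- list()
  newy <- integer(0)
  with_seed(seed, {
    for (cl in as.integer(names(tab))) {
      m <- tab[[as.character(cl)]]
      need <- target - m
      if (need == 0L) next
      Xc <- X[y == cl, , drop = FALSE]
      if (m == 1L) {
        newX[[length(newX) + 1L]] <-
          Xc[rep(1L, need), , drop = FALSE]
        newy <- c(newy, rep(cl, need))
        next
      }
      kc <- min(k, m - 1L)
      D <- as.matrix(stats::dist(sweep(Xc, 2L, sds, "/")))
      nn <- t(apply(D, 1L, function(d) order(d)[2:(kc + 1L)]))
      syn <- matrix(0, need, ncol(X))
      for (j in seq_len(need)) {
        i <- sample.int(m, 1L)
        nb <- nn[i, if (kc == 1L) 1L else sample.int(kc, 1L)]
        u <- stats::runif(1L)
        syn[j, ] <- Xc[i, ] + u * (Xc[nb, ] - Xc[i, ])
      }
      newX[[length(newX) + 1L]] <- syn
      newy <- c(newy, rep(cl, need))
    }
  })
  if (length(newX)) {
    Xs <- do.call(rbind, newX)
    colnames(Xs) <- colnames(X)
    list(X = rbind(X, Xs), y = c(y, newy),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs))))
  } else {
    list(X = X, y = y, synthetic = rep(FALSE, nrow(X)))
  }
}

#' Published hyperparameter grids
#'
#' Gradient-boosted trees: learning rate \{0.05, 0.1\}, depth \{3, 4\}, gamma
#' \{0.1, 0.2\}, L2 lambda \{3, 4, 5\}; RBF max-margin classifier: gamma
#' \{0.001, 0.01, 0.1, 1\}, cost \{0.1, 1, 10, 100\}.
#'
#' @return list `gbt`, `svm` of data frames.
#' @export
default_grids <- function() {
  list(
    gbt = expand.grid(eta = c(0.05, 0.1), max_depth = c(3L, 4L),
                      gamma = c(0.1, 0.2), lambda = c(3, 4, 5)),
    svm = expand.grid(gamma = c(0.001, 0.01, 0.1, 1),
                      cost = c(0.1, 1, 10, 100))
  )
}

#' Compact hyperparameter grids for the bundled synthetic study
#'
#' A 4 + 4 subset of [default_grids()] (GBT: eta x lambda at depth 3, gamma
#' 0.1; SVM: gamma \{0.01, 0.1\} x cost \{1, 10\}) keeping the study's
#' leave-one-out grid search tractable on one CPU.
#'
#' @return list `gbt`, `svm` of data frames.
#' @export
compact_grids <- function() {
  list(
    gbt = expand.grid(eta = c(0.05, 0.1), max_depth = 3L, gamma = 0.1,
                      lambda = c(3, 5)),
    svm = expand.grid(gamma = c(0.01, 0.1), cost = c(1, 10))
  )
}

# fixed reference hyperparameters for the ranking fit (lowest grid corner)
ranking_params <- function(M, nthread = 1L) {
  list(objective = "multi:softmax", num_class = M, eta = 0.1, max_depth = 3L,
       gamma = 0.1, lambda = 3, nthread = nthread, tree_method = "hist",
       max_bin = 64L)
}

# locale-independent (byte order) rank of names, for deterministic tie-breaks
c_order_rank <- function(x) {
  x <- enc2utf8(x) # radix sort requires a marked encoding
  match(x, sort(unique(x), method = "radix"))
}

#' Rank features by total Gain of a reference gradient-boosted fit
#'
#' One gradient-boosted model with fixed reference hyperparameters (learning
#' rate 0.1, depth 3, gamma 0.1, lambda 3) is fitted on the full training set;
#' features are ordered by decreasing total Gain, with lexicographic name
#' tie-breaks. Features never used by the model receive Gain 0.
#'
#' @param X training feature matrix/data frame (complete; impute first).
#' @param y merged level labels `0..M-1`.
#' @param seed integer seed.
#' @param nrounds boosting rounds of the reference fit.
#' @return data frame `feature`, `gain`, ordered most to least important.
#' @export
rank_features_by_gain <- function(X, y, seed = 1L, nrounds = 100) {
  X <- as.matrix(X)
  nm <- colnames(X)
  stopifnot(!is.null(nm))
  Xs <- X
  colnames(Xs) <- sprintf("f%05d", seq_along(nm))
  M <- max(y) + 1L
  booster <- with_seed(seed, {
    dm <- xgboost::xgb.DMatrix(Xs, label = y, nthread = 1L)
    xgboost::xgb.train(ranking_params(M), dm, nrounds = nrounds, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  gain <- stats::setNames(rep(0, length(nm)), colnames(Xs))
  gain[imp$Feature] <- imp$Gain
  out <- data.frame(feature = nm, gain = as.numeric(gain))
  out[order(-out$gain, c_order_rank(out$feature)), , drop = FALSE]
}

# median-impute columns of a matrix using given medians
impute_medians <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- med[j]
  }
  X
}

col_medians <- function(X) {
  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

fit_one <- function(algorithm, params, X, y, M, nrounds, seed) {
  if (algorithm == "gbt") {
    p <- list(objective = "multi:softmax", num_class = M, eta = params$eta,
              max_depth = params$max_depth, gamma = params$gamma,
              lambda = params$lambda, nthread = 1L, tree_method = "hist",
              max_bin = 32L)
    with_seed(seed, {
      dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1L)
      xgboost::xgb.train(p, dm, nrounds = nrounds, verbose = 0)
    })
  } else {
    e1071::svm(X, factor(y, levels = 0:(M - 1L)), kernel = "radial",
               gamma = params$gamma, cost = params$cost, scale = FALSE)
  }
}

predict_one <- function(algorithm, fit, Xnew) {
  if (algorithm == "gbt") {
    as.integer(predict(fit, xgboost::xgb.DMatrix(Xnew, nthread = 1L)))
  } else {
    as.integer(as.character(predict(fit, Xnew)))
  }
}

#' Leave-one-out cross-validation with SMOTE inside every fold
#'
#' For each fold, the left-out participant is removed first; median imputation,
#' standardization and SMOTE are fitted on the remaining training subset only,
#' so the left-out sample never enters the oversampling (no leakage). All
#' feature-count/hyperparameter configurations are evaluated on the same fold
#' stream, predictions are pooled into one confusion matrix per configuration
#' and scored with the ordinal metrics.
#'
#' @param X training feature matrix/data frame (named columns; NAs allowed).
#' @param y merged level labels `0..M-1`.
#' @param ranked_features feature names ordered by Gain (from
#'   [rank_features_by_gain()]).
#' @param k_grid feature counts to evaluate (top-K of the ranking).
#' @param grids list `gbt`, `svm` of hyperparameter data frames (NULL element
#'   skips that algorithm).
#' @param seed integer seed.
#' @param nrounds boosting rounds per gradient-boosted fit.
#' @param smote_k SMOTE neighbour count.
#' @param fold_callback optional `function(left_out, train_idx, smote_idx)`
#'   called once per (K, fold) with the row indices used for oversampling;
#'   used by the structural no-leakage checks.
#' @return list of class `loocv_result`: `results` (one row per
#'   configuration with metrics), `preds` (list of per-configuration LOOCV
#'   prediction vectors), `n_flagged_folds` (folds whose training subset
#'   missed a class), `M`.
#' @export
loocv_evaluate <- function(X, y, ranked_features, k_grid = seq(5, 50, by = 5),
                           grids = default_grids(), seed = 1L, nrounds = 30,
                           smote_k = 5, fold_callback = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  M <- max(y) + 1L
  stopifnot(max(k_grid) <= length(ranked_features))
  configs <- list()
  for (K in k_grid) {
    if (!is.null(grids$gbt)) for (r in seq_len(nrow(grids$gbt)))
      configs[[length(configs) + 1L]] <-
        c(list(algorithm = "gbt", K = K), as.list(grids$gbt[r, ]))
    if (!is.null(grids$svm)) for (r in seq_len(nrow(grids$svm)))
      configs[[length(configs) + 1L]] <-
        c(list(algorithm = "svm", K = K), as.list(grids$svm[r, ]))
  }
  preds <- lapply(configs, function(cf) rep(NA_integer_, n))
  flagged <- 0L
  for (K in unique(k_grid)) {
    feats <- ranked_features[seq_len(K)]
    Xk <- X[, feats, drop = FALSE]
    kconf <- which(vapply(configs, function(cf) cf$K == K, TRUE))
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      Xtr <- Xk[tr, , drop = FALSE]
      ytr <- y[tr]
      if (length(unique(ytr)) < M) flagged <- flagged + 1L
      med <- col_medians(Xtr)
      Xtr <- impute_medians(Xtr, med)
      ctr <- colMeans(Xtr)
      sdev <- apply(Xtr, 2L, stats::sd)
      sdev[!is.finite(sdev) | sdev == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, ctr), 2L, sdev, "/")
      Xte <- impute_medians(Xk[i, , drop = FALSE], med)
      Xte <- sweep(sweep(Xte, 2L, ctr), 2L, sdev, "/")
      sm <- smote_balance(Xtr, ytr, k = smote_k,
                          seed = derive_seed(seed, "smote", K, i))
      if (!is.null(fold_callback)) fold_callback(i, tr, which(!sm$synthetic))
      dm <- NULL
      for (ci in kconf) {
        cf <- configs[[ci]]
        if (cf$algorithm == "gbt" && is.null(dm))
          dm <- xgboost::xgb.DMatrix(sm$X, label = sm$y, nthread = 1L)
        fit <- if (cf$algorithm == "gbt") {
          p <- list(objective = "multi:softmax", num_class = M, eta = cf$eta,
                    max_depth = cf$max_depth, gamma = cf$gamma,
                    lambda = cf$lambda, nthread = 1L, tree_method = "hist",
                    max_bin = 32L)
          xgboost::xgb.train(p, dm, nrounds = nrounds, verbose = 0)
        } else {
          e1071::svm(sm$X, factor(sm$y, levels = 0:(M - 1L)),
                     kernel = "radial", gamma = cf$gamma, cost = cf$cost,
                     scale = FALSE)
        }
        preds[[ci]][i] <- predict_one(cf$algorithm, fit, Xte)
      }
    }
  }
  rows <- lapply(seq_along(configs), function(ci) {
    cf <- configs[[ci]]
    cm <- confusion_matrix(y, preds[[ci]], M)
    rep <- item_report(cm)
    data.frame(
      config = ci, algorithm = cf$algorithm, K = cf$K,
      eta = cf$eta %||% NA, max_depth = cf$max_depth %||% NA,
      gamma = cf$gamma %||% NA, lambda = cf$lambda %||% NA,
      cost = cf$cost %||% NA,
      weighted_f1 = rep$weighted_f1, acc0 = rep$acc_exact,
      acc1 = rep$acc_within1, kappa_w = rep$kappa_w, macro_f1 = rep$macro_f1
    )
  })
  structure(list(results = do.call(rbind, rows), preds = preds,
                 configs = configs, n_flagged_folds = flagged, M = M, y = y),
            class = "loocv_result")
}

#' Select the best configuration from LOOCV results
#'
#' Argmax of weighted F1; ties broken by exact accuracy, then smaller K, then
#' algorithm order (gradient-boosted trees before the RBF classifier).
#'
#' @param cv a `loocv_result`.
#' @return list: the winning configuration (`algorithm`, `K`, hyperparameters)
#'   plus `metrics` (its results row) and `loocv_cm` (its pooled confusion
#'   matrix).
#' @export
select_best <- function(cv) {
  stopifnot(inherits(cv, "loocv_result"))
  r <- cv$results
  stopifnot(nrow(r) >= 1L)
  alg_rank <- match(r$algorithm, c("gbt", "svm"))
  ord <- order(-r$weighted_f1, -r$acc0, r$K, alg_rank)
  best <- r[ord[1L], ]
  cf <- cv$configs[[best$config]]
  cf$metrics <- best
  cf$loocv_cm <- confusion_matrix(cv$y, cv$preds[[best$config]], cv$M)
  cf
}

#' Refit the selected configuration on the whole training set
#'
#' Median imputation, standardization and SMOTE are fitted on the full
#' training set (the same oversampling procedure as inside LOOCV), then the
#' winning model is trained and packaged with everything needed to predict
#' new participants.
#'
#' @param X training feature matrix (named columns).
#' @param y merged levels `0..M-1`.
#' @param best configuration from [select_best()].
#' @param seed integer seed.
#' @param nrounds boosting rounds (gradient-boosted algorithm).
#' @param smote_k SMOTE neighbour count.
#' @return object of class `item_model`.
#' @export
fit_final <- function(X, y, best, seed = 1L, nrounds = 30, smote_k = 5) {
  X <- as.matrix(X)
  feats <- colnames(X)
  M <- max(y) + 1L
  med <- col_medians(X)
  Xi <- impute_medians(X, med)
  ctr <- colMeans(Xi)
  sdev <- apply(Xi, 2L, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  Xs <- sweep(sweep(Xi, 2L, ctr), 2L, sdev, "/")
  sm <- smote_balance(Xs, y, k = smote_k, seed = derive_seed(seed, "final"))
  fit <- fit_one(best$algorithm, best, sm$X, sm$y, M, nrounds,
                 derive_seed(seed, "final_fit"))
  structure(list(algorithm = best$algorithm, K = length(feats),
                 features = feats, params = best[setdiff(names(best),
                   c("metrics", "loocv_cm", "algorithm", "K"))],
                 medians = med, center = ctr, scale = sdev, M = M, fit = fit),
            class = "item_model")
}

#' @export
predict.item_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  X <- impute_medians(X, object$medians)
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  predict_one(object$algorithm, object$fit, X)
}

#' Save / load an item model (portable serialization)
#'
#' Gradient-boosted boosters are serialized through their raw format so a
#' round-trip reproduces identical predictions.
#'
#' @param model an `item_model`.
#' @param path file path.
#' @return `path` (save) or the restored `item_model` (load).
#' @export
save_item_model <- function(model, path) {
  stopifnot(inherits(model, "item_model"))
  if (model$algorithm == "gbt") model$fit <- xgboost::xgb.save.raw(model$fit)
  saveRDS(model, path)
  path
}

#' @rdname save_item_model
#' @export
load_item_model <- function(path) {
  model <- readRDS(path)
  if (model$algorithm == "gbt") model$fit <- xgboost::xgb.load.raw(model$fit)
  model
}

#' Per-sensor-group contribution of a trained item model
#'
#' The proportion of the model's selected features derived from each sensor
#' group (waist, chest, hand, thigh, shank, foot; left/right grouped).
#' Features built from several sensors count once per group, so contributions
#' can sum beyond 100 percent.
#'
#' @param model an `item_model` (or character vector of feature names).
#' @param registry feature catalogue, see [feature_registry()].
#' @return named numeric vector of percentages.
#' @export
sensor_contribution <- function(model, registry = feature_registry()) {
  feats <- if (inherits(model, "item_model")) model$features else model
  bases <- constructed_base(feats)
  idx <- match(bases, registry$base)
  if (anyNA(idx))
    stop("unregistered feature(s): ",
         paste(unique(feats[is.na(idx)]), collapse = ", "))
  groups <- c("waist", "chest", "hand", "thigh", "shank", "foot")
  cnt <- stats::setNames(numeric(length(groups)), groups)
  for (s in registry$sensors[idx]) {
    for (gp in strsplit(s, ",")[[1L]]) cnt[gp] <- cnt[gp] + 1
  }
  100 * cnt / length(feats)
}
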