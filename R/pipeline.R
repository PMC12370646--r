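#' Match detected gait events to ground truth
#'
#' Each detected event is matched to the nearest ground-truth event of the
#' same side and type; absolute timing errors are reported together with the
#' fraction within tolerance.
#'
#' @param pred detected event table (`side`, `type`, `sample`).
#' @param truth ground-truth event table (same columns).
#' @param fs sampling rate in Hz.
#' @param tol_s tolerance in seconds (default 20 ms).
#' @param kinds restrict to section kinds (default straight walks, where
#'   event timing is defined sharply).
#' @return list `errors` (seconds), `frac_within`, `n_pred`, `n_truth`.
#' @export
match_event_times <- function(pred, truth, fs, tol_s = 0.02, kinds = "SW") {
  if ("kind" %in% names(pred)) pred <- pred[pred$kind %in% kinds, , drop = FALSE]
  if ("kind" %in% names(truth)) truth <- truth[truth$kind %in% kinds, , drop = FALSE]
  errs <- numeric(0)
  for (side in unique(pred$side)) {
    for (type in unique(pred$type)) {
      p <- pred$sample[pred$side == side & pred$type == type]
      t <- truth$sample[truth$side == side & truth$type == type]
      if (length(p) == 0L || length(t) == 0L) next
      errs <- c(errs, vapply(p, function(s) min(abs(s - t)) / fs, 1.0))
    }
  }
  list(errors = errs,
       frac_within = if (length(errs)) mean(errs <= tol_s) else NA_real_,
       n_pred = nrow(pred), n_truth = nrow(truth))
}

#' Simulate a cohort and extract its constructed feature table
#'
#' Streams participants one at a time (simulate, preprocess, segment, detect
#' events, construct features, discard the raw recording), so large cohorts
#' fit in memory. Seeds per participant are derived from `seed` exactly as in
#' [simulate_cohort()].
#'
#' @param n cohort size.
#' @param cfg a [protocol_config()].
#' @param seed cohort seed.
#' @param rater_noise_sd rater noise SD for the item labels.
#' @param mix severity mix overrides (see [simulate_cohort()]).
#' @param diagnostics also compute per-participant segmentation boundary and
#'   event-timing recovery against ground truth.
#' @return list: `features` (data frame, first column `participant`, then the
#'   constructed features), `labels`, `diagnostics` (or NULL).
#' @export
cohort_feature_table <- function(n, cfg = protocol_config(), seed = 1L,
                                 rater_noise_sd = 0.3, mix = list(),
                                 diagnostics = FALSE) {
  profiles <- sample_severity_profiles(
    n, seed = derive_seed(seed, "profiles"),
    mu = mix$mu %||% -1.0, sd = mix$sd %||% 1.0, rho = mix$rho %||% 0.7
  )
  ids <- sprintf("P%03d", seq_len(n))
  feat_rows <- vector("list", n)
  labels <- vector("list", n)
  diag_rows <- if (diagnostics) vector("list", n) else NULL
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$rng_seed <- derive_seed(seed, "participant", i)
    sim <- simulate_participant(profiles[[i]], cfg_i, participant_id = ids[i])
    scores <- assign_item_scores(profiles[[i]], rater_noise_sd,
                                 seed = derive_seed(seed, "rater", i))
    labels[[i]] <- data.frame(
      participant = ids[i], t(scores), age = profiles[[i]]$age,
      sex = profiles[[i]]$sex, pd_duration = profiles[[i]]$pd_duration
    )
    ex <- extract_participant_features(sim$recording,
                                       path_length_m = cfg$path_length_m)
    feat_rows[[i]] <- ex$features
    if (diagnostics) {
      seg <- match_to_ground_truth(ex$sections, sim$truth$sections,
                                   tol_s = 0.25, fs = cfg$fs_hz)
      evm <- match_event_times(ex$events, sim$truth$events, fs = cfg$fs_hz)
      diag_rows[[i]] <- data.frame(
        participant = ids[i],
        seg_frac_within = seg$frac_within,
        seg_max_err_s = max(seg$boundaries$err_s),
        n_sections = nrow(ex$sections),
        ev_frac_within = evm$frac_within,
        ev_max_err_s = if (length(evm$errors)) max(evm$errors) else NA_real_
      )
    }
  }
  all_names <- unique(unlist(lapply(feat_rows, names)))
  mat <- matrix(NA_real_, n, length(all_names),
                dimnames = list(NULL, all_names))
  for (i in seq_len(n)) mat[i, names(feat_rows[[i]])] <- feat_rows[[i]]
  features <- data.frame(participant = ids, mat, check.names = FALSE)
  list(features = features, labels = do.call(rbind, labels),
       diagnostics = if (diagnostics) do.call(rbind, diag_rows) else NULL)
}

#' Train the five item models and the subscale model
#'
#' For each item: merge sparse levels on the training set, rank features by
#' Gain, run the SMOTE-in-LOOCV grid search over feature counts and
#' hyperparameters, select the best configuration, refit on the full training
#' set and evaluate on the held-out test set. The subscale model is the LASSO
#' regression on the training set, evaluated on test.
#'
#' @param features constructed feature table (`participant` + features).
#' @param labels label table (`participant`, item columns, demographics).
#' @param split output of [split_cohort()].
#' @param items item columns to model.
#' @param k_grid feature counts (top-K) to evaluate.
#' @param grids hyperparameter grids (see [default_grids()],
#'   [compact_grids()]).
#' @param seed integer seed.
#' @param nrounds boosting rounds.
#' @param min_n merge threshold for sparse levels.
#' @return list of class `gait_models`: per-item results (`merge_map`,
#'   `ranking`, `cv`, `best`, `model`, `loocv_report`, `test_report`,
#'   `sensor_contribution`) under `items`, plus `subscale` (`model`,
#'   `train_report`, `test_report`) and `split`.
#' @export
train_item_models <- function(features, labels, split,
                              items = item_names(),
                              k_grid = seq(5, 50, by = 5),
                              grids = default_grids(), seed = 1L,
                              nrounds = 30, min_n = 5) {
  stopifnot(identical(sort(features$participant), sort(labels$participant)))
  rownames(features) <- features$participant
  rownames(labels) <- labels$participant
  Xall <- as.matrix(features[, setdiff(names(features), "participant"),
                             drop = FALSE])
  tr <- split$train_ids
  te <- split$test_ids
  out <- list()
  for (it in items) {
    y_tr_raw <- labels[tr, it]
    mm <- merge_levels(y_tr_raw, min_n = min_n)
    y_tr <- apply_merge(y_tr_raw, mm)
    y_te <- apply_merge(labels[te, it], mm)
    Xtr <- Xall[tr, , drop = FALSE]
    med <- col_medians(Xtr)
    ranking <- rank_features_by_gain(impute_medians(Xtr, med), y_tr,
                                     seed = derive_seed(seed, it, "rank"))
    cv <- loocv_evaluate(Xtr, y_tr, ranking$feature, k_grid = k_grid,
                         grids = grids, seed = derive_seed(seed, it, "cv"),
                         nrounds = nrounds)
    best <- select_best(cv)
    model <- fit_final(Xtr[, ranking$feature[seq_len(best$K)], drop = FALSE],
                       y_tr, best, seed = derive_seed(seed, it, "final"),
                       nrounds = nrounds)
    model$merge_map <- mm
    model$item <- it
    pred_te <- predict(model, Xall[te, , drop = FALSE])
    out[[it]] <- list(
      item = it, merge_map = mm, ranking = ranking, cv = cv$results,
      best = best, model = model,
      loocv_report = item_report(best$loocv_cm),
      test_report = item_report(confusion_matrix(y_te, pred_te, mm$M)),
      sensor_contribution = sensor_contribution(model)
    )
  }
  subscale_tr <- rowSums(labels[tr, item_names()])
  subscale_te <- rowSums(labels[te, item_names()])
  sub <- fit_subscale(Xall[tr, , drop = FALSE], subscale_tr,
                      seed = derive_seed(seed, "subscale"))
  sub_pred_tr <- predict(sub, Xall[tr, , drop = FALSE])
  sub_pred_te <- predict(sub, Xall[te, , drop = FALSE])
  structure(list(
    items = out, split = split,
    subscale = list(model = sub,
                    train_report = regression_metrics(subscale_tr, sub_pred_tr),
                    test_report = regression_metrics(subscale_te, sub_pred_te))
  ), class = "gait_models")
}

#' Configuration of the full synthetic-study pipeline
#'
#' @param n cohort size.
#' @param seed global seed; stage seeds are derived from it.
#' @param cfg protocol configuration.
#' @param rater_noise_sd rater noise SD.
#' @param k_grid,grids,nrounds modeling settings (defaults: the bundled
#'   study's reduced K grid and compact hyperparameter grids).
#' @param train_frac training fraction of the split.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n = 200, seed = 1L, cfg = protocol_config(),
                            rater_noise_sd = 0.3, k_grid = c(5, 15, 25),
                            grids = compact_grids(), nrounds = 30,
                            train_frac = 0.8) {
  structure(list(n = n, seed = as.integer(seed), cfg = cfg,
                 rater_noise_sd = rater_noise_sd, k_grid = k_grid,
                 grids = grids, nrounds = nrounds, train_frac = train_frac),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, extract, split, train, evaluate
#'
#' Stages run in order with seeds derived from the global seed. When
#' `out_dir` is given, stage outputs are written as CSV and a JSON manifest
#' records seeds, problem sizes and file MD5 hashes; an existing feature
#' table is reused (`skip_existing = TRUE`) when its inputs are unchanged.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param skip_existing reuse `features.csv`/`labels.csv` from `out_dir` if
#'   present.
#' @return list: `features`, `labels`, `split`, `models` (a `gait_models`),
#'   `summary` (per-item metric table), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         skip_existing = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  feats_file <- if (!is.null(out_dir)) file.path(out_dir, "features.csv")
  labels_file <- if (!is.null(out_dir)) file.path(out_dir, "labels.csv")
  if (skip_existing && !is.null(out_dir) && file.exists(feats_file) &&
      file.exists(labels_file)) {
    features <- as.data.frame(data.table::fread(feats_file, check.names = FALSE))
    labels <- as.data.frame(data.table::fread(labels_file))
    ct <- list(features = features, labels = labels)
  } else {
    ct <- cohort_feature_table(config$n, config$cfg,
                               seed = derive_seed(config$seed, "cohort"),
                               rater_noise_sd = config$rater_noise_sd)
  }
  split <- split_cohort(ct$labels, train_frac = config$train_frac,
                        seed = derive_seed(config$seed, "split"))
  models <- train_item_models(ct$features, ct$labels, split,
                              k_grid = config$k_grid, grids = config$grids,
                              seed = derive_seed(config$seed, "train"),
                              nrounds = config$nrounds)
  summarize <- function(it) {
    r <- models$items[[it]]
    data.frame(
      item = it, M = r$merge_map$M, algorithm = r$best$algorithm,
      K = r$best$K,
      loocv_weighted_f1 = r$loocv_report$weighted_f1,
      loocv_acc0 = r$loocv_report$acc_exact,
      loocv_acc1 = r$loocv_report$acc_within1,
      loocv_kappa_w = r$loocv_report$kappa_w,
      test_weighted_f1 = r$test_report$weighted_f1,
      test_acc0 = r$test_report$acc_exact,
      test_acc1 = r$test_report$acc_within1,
      test_kappa_w = r$test_report$kappa_w
    )
  }
  summary <- do.call(rbind, lapply(names(models$items), summarize))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitupdrs")),
    seed = config$seed, n = config$n,
    k_grid = config$k_grid, nrounds = config$nrounds,
    n_features = ncol(ct$features) - 1L,
    items = item_names()
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(ct$features, feats_file)
    data.table::fwrite(ct$labels, labels_file)
    data.table::fwrite(summary, file.path(out_dir, "item_metrics.csv"))
    sub <- models$subscale
    data.table::fwrite(data.frame(
      set = c("train_loofit", "test"),
      mae = c(sub$train_report$mae, sub$test_report$mae),
      rmse = c(sub$train_report$rmse, sub$test_report$rmse),
      spearman_r = c(sub$train_report$spearman_r, sub$test_report$spearman_r)
    ), file.path(out_dir, "subscale_metrics.csv"))
    files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
    manifest$file_md5 <- as.list(tools::md5sum(files))
    names(manifest$file_md5) <- basename(files)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  list(features = ct$features, labels = ct$labels, split = split,
       models = models, summary = summary, manifest = manifest)
}
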