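#!/usr/bin/env Rscript
# Train the five ordinal item models: balanced split, score-level merging,
# Gain ranking, SMOTE-in-LOOCV grid search (reduced K grid and compact
# hyperparameter grids), final refit and held-out evaluation. Also writes the
# per-sensor contributions and the feature-score correlations of a few
# clinically interpretable features.

suppressMessages(library(gaitupdrs))
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/features.csv"))
  stop("run analysis/03_extract_features.R first")

features <- as.data.frame(data.table::fread("results/features.csv",
                                            check.names = FALSE))
labels <- as.data.frame(data.table::fread("results/labels.csv"))

split <- split_cohort(labels, seed = 2L)
models <- train_item_models(features, labels, split, k_grid = c(5, 15, 25),
                            grids = compact_grids(), seed = 3L)

summary <- do.call(rbind, lapply(models$items, function(r) data.frame(
  item = r$item, levels = paste(r$merge_map$labels, collapse = "|"),
  algorithm = r$best$algorithm, K = r$best$K,
  loocv_weighted_f1 = round(r$loocv_report$weighted_f1, 3),
  loocv_acc0 = round(r$loocv_report$acc_exact, 1),
  loocv_acc1 = round(r$loocv_report$acc_within1, 1),
  test_weighted_f1 = round(r$test_report$weighted_f1, 3),
  test_acc0 = round(r$test_report$acc_exact, 1),
  test_acc1 = round(r$test_report$acc_within1, 1),
  test_kappa_w = round(r$test_report$kappa_w, 3)
)))
data.table::fwrite(summary, "results/item_metrics.csv")
print(summary, row.names = FALSE)

contrib <- do.call(rbind, lapply(models$items, function(r)
  data.frame(item = r$item, t(round(r$sensor_contribution, 1)))))
data.table::fwrite(contrib, "results/sensor_contributions.csv")

# feature-score correlations with known clinical reading
pairs <- list(
  c("Shank—Swing RoM—mean (max)", "item_3_10"),
  c("180° Turn—Steps—mean", "item_3_11"),
  c("180° Turn—Duration—mean", "item_3_12"),
  c("Trunk—Forward Sway Max—max", "item_3_13"),
  c("Effective Trial Duration", "item_3_10")
)
cors <- do.call(rbind, lapply(pairs, function(p) {
  fsc <- feature_score_correlation(features[[p[1]]], labels[[p[2]]])
  data.frame(feature = p[1], item = p[2], spearman_r = round(fsc$r, 3),
             p_value = signif(fsc$p, 3), band = fsc$band)
}))
data.table::fwrite(cors, "results/feature_correlations.csv")
cat("\nfeature-score correlations:\n")
print(cors, row.names = FALSE)
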