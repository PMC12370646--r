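#!/usr/bin/env Rscript
# LASSO regression of the gait-and-posture subscale (sum of the five item
# scores) on the constructed features, with lambda at the minimum mean
# 10-fold cross-validated error; evaluated on the held-out test set.

suppressMessages(library(gaitupdrs))
dir.create("results", showWarnings = FALSE)
if (!file.exists("results/features.csv"))
  stop("run analysis/03_extract_features.R first")

features <- as.data.frame(data.table::fread("results/features.csv",
                                            check.names = FALSE))
labels <- as.data.frame(data.table::fread("results/labels.csv"))
rownames(features) <- features$participant
rownames(labels) <- labels$participant

split <- split_cohort(labels, seed = 2L)
X <- as.matrix(features[, -1])
y <- rowSums(labels[, item_names()])

sub <- fit_subscale(X[split$train_ids, ], y[split$train_ids], seed = 4L)
pred <- predict(sub, X[split$test_ids, ])
rep <- regression_metrics(y[split$test_ids], pred)

cat("lambda (min CV error):", signif(sub$lambda, 4), "\n")
cat("non-zero features:", length(sub$features), "\n")
cat(sprintf("test MAE %.3f, RMSE %.3f, Spearman R %.3f (%s)\n",
            rep$mae, rep$rmse, rep$spearman_r, rep$correlation_band))

data.table::fwrite(data.frame(
  lambda = sub$lambda, n_features = length(sub$features),
  test_mae = rep$mae, test_rmse = rep$rmse, test_spearman = rep$spearman_r
), "results/subscale_metrics.csv")
data.table::fwrite(data.frame(feature = sub$features,
                              beta = unname(sub$beta)),
                   "results/subscale_coefficients.csv")
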