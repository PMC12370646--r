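#' Confusion matrix on merged ordinal levels
#'
#' @param true,pred integer vectors of merged levels `0..M-1`.
#' @param M number of merged levels (default: inferred).
#' @return `M x M` integer matrix, rows = true level, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, M = NULL) {
  stopifnot(length(true) == length(pred))
  M <- M %||% (max(c(true, pred)) + 1L)
  cm <- matrix(0L, M, M, dimnames = list(true = 0:(M - 1L),
                                         pred = 0:(M - 1L)))
  for (i in seq_along(true)) cm[true[i] + 1L, pred[i] + 1L] <-
      cm[true[i] + 1L, pred[i] + 1L] + 1L
  cm
}

#' Per-class precision, recall and F1 with explicit undefined conventions
#'
#' Precision is undefined (`NA`) for a class never predicted; recall is 0 for
#' a class present but never hit, and undefined for a class absent from the
#' data; F1 is defined only when both precision and recall are defined and
#' their sum is positive (so a class with precision = recall = 0 has
#' undefined F1).
#'
#' @param cm confusion matrix (rows true, columns predicted).
#' @return data frame `class, precision, recall, f1, support`.
#' @export
per_class_metrics <- function(cm) {
  M <- nrow(cm)
  tp <- diag(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  precision <- ifelse(cs > 0, tp / cs, NA_real_)
  recall <- ifelse(rs > 0, tp / rs, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  data.frame(class = 0:(M - 1L), precision = precision, recall = recall,
             f1 = f1, support = as.integer(rs))
}

#' Support-weighted mean F1
#'
#' Classes with undefined F1 contribute 0 to the numerator while their support
#' stays in the denominator (the convention consistent with published
#' item-model tables containing NA rows).
#'
#' @param class_metrics output of [per_class_metrics()].
#' @return weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(class_metrics) {
  s <- class_metrics$support
  if (sum(s) == 0) stop("no class with positive support")
  f <- ifelse(is.na(class_metrics$f1), 0, class_metrics$f1)
  sum(f * s) / sum(s)
}

#' Macro F1
#'
#' Unweighted mean over classes whose F1 is defined; errors if none is.
#'
#' @param class_metrics output of [per_class_metrics()].
#' @return macro F1 in `[0, 1]`.
#' @export
macro_f1 <- function(class_metrics) {
  f <- class_metrics$f1[!is.na(class_metrics$f1)]
  if (length(f) == 0L) stop("all class F1 scores are undefined")
  mean(f)
}

#' Accuracy within k levels
#'
#' `ACC+-0` is exact accuracy; `ACC+-1` the share of predictions within one
#' merged level of the truth. Distances are measured on merged-level indices.
#'
#' @param cm confusion matrix.
#' @param k allowed absolute level distance (0 or 1).
#' @return percentage in `[0, 100]`.
#' @export
acc_within <- function(cm, k = 0) {
  M <- nrow(cm)
  d <- abs(outer(seq_len(M), seq_len(M), "-"))
  100 * sum(cm[d <= k]) / sum(cm)
}

#' Cohen's weighted kappa with quadratic weights
#'
#' Disagreement weights `w_ij = ((i - j)/(M - 1))^2` penalize larger ordinal
#' disagreements more. Undefined (`NA`) when the chance disagreement is zero
#' (degenerate marginals).
#'
#' @param cm confusion matrix, `M >= 2`.
#' @return kappa in `[-1, 1]`, or `NA`.
#' @export
weighted_kappa <- function(cm) {
  M <- nrow(cm)
  stopifnot(M >= 2L)
  n <- sum(cm)
  w <- (outer(seq_len(M), seq_len(M), "-") / (M - 1))^2
  obs <- sum(w * cm) / n
  expd <- sum(w * outer(rowSums(cm), colSums(cm))) / n^2
  if (expd == 0) return(NA_real_)
  1 - obs / expd
}

#' Agreement band for a weighted kappa value
#'
#' The printed interpretation scale: <0 poor; 0-0.20 slight; 0.21-0.40 fair;
#' 0.41-0.60 moderate; 0.61-0.80 substantial; 0.81-1.00 almost perfect.
#'
#' @param k kappa value.
#' @return character band label.
#' @export
kappa_band <- function(k) {
  if (is.na(k)) return(NA_character_)
  if (k < 0) "poor agreement"
  else if (k <= 0.20) "slight agreement"
  else if (k <= 0.40) "fair agreement"
  else if (k <= 0.60) "moderate agreement"
  else if (k <= 0.80) "substantial agreement"
  else "almost perfect agreement"
}

#' Correlation band for a Spearman coefficient
#'
#' 0-0.10 negligible; 0.10-0.39 weak; 0.40-0.69 moderate; 0.70-0.89 strong;
#' 0.90-1.00 very strong (absolute value).
#'
#' @param r correlation value.
#' @return character band label.
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  if (is.na(a)) return(NA_character_)
  if (a < 0.10) "negligible correlation"
  else if (a < 0.40) "weak correlation"
  else if (a < 0.70) "moderate correlation"
  else if (a < 0.90) "strong correlation"
  else "very strong correlation"
}

#' Full ordinal classification report for one item
#'
#' @param cm confusion matrix on merged levels.
#' @return list of class `item_report`: `weighted_f1, macro_f1, acc_exact,
#'   acc_within1, kappa_w, kappa_band, per_class, n`.
#' @export
item_report <- function(cm) {
  pcm <- per_class_metrics(cm)
  kw <- weighted_kappa(cm)
  structure(list(
    weighted_f1 = weighted_f1(pcm),
    macro_f1 = macro_f1(pcm),
    acc_exact = acc_within(cm, 0),
    acc_within1 = acc_within(cm, 1),
    kappa_w = kw,
    kappa_band = kappa_band(kw),
    per_class = pcm,
    n = sum(cm)
  ), class = "item_report")
}

#' Regression report: MAE, RMSE and Spearman correlation
#'
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((yhat - y)^2))`; Spearman rank
#' correlation uses average ranks on ties. Spearman was preferred over Pearson
#' because subscale scores are ordinal sums with non-normal distributions.
#'
#' @param y true scores.
#' @param yhat predicted scores.
#' @return list of class `regression_report`: `mae, rmse, spearman_r,
#'   correlation_band, n`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  if (length(y) < 2L) stop("need at least 2 observations")
  r <- suppressWarnings(stats::cor(y, yhat, method = "spearman"))
  structure(list(
    mae = mean(abs(y - yhat)),
    rmse = sqrt(mean((yhat - y)^2)),
    spearman_r = r,
    correlation_band = correlation_band(r),
    n = length(y)
  ), class = "regression_report")
}

#' Reconstruct aggregate metrics from printed per-class values
#'
#' Given per-class precision, recall and support as printed (3 decimals), the
#' per-class F1 is recomputed as their harmonic mean, the per-class true
#' positives as `round(recall * support)`, and the aggregates follow the
#' package conventions ([weighted_f1()], [macro_f1()]); exact accuracy is
#' `100 * sum(TP) / sum(support)`. A recall whose product with support is far
#' from an integer triggers a printed-rounding warning.
#'
#' @param precision,recall numeric per-class values (`NA` allowed for
#'   precision of never-predicted classes).
#' @param support positive integer per-class counts.
#' @return list: `per_class_f1, weighted_f1, macro_f1, acc_exact`.
#' @export
reconstruct_from_table <- function(precision, recall, support) {
  stopifnot(length(precision) == length(recall),
            length(recall) == length(support))
  if (any(support <= 0 | support != round(support)))
    stop("supports must be positive integers")
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  tp_raw <- recall * support
  if (any(abs(tp_raw - round(tp_raw)) > 0.45, na.rm = TRUE))
    warning("recall * support far from an integer: printed rounding inconsistency")
  tp <- round(tp_raw)
  cmx <- data.frame(f1 = f1, support = as.integer(support))
  list(
    per_class_f1 = f1,
    weighted_f1 = sum(ifelse(is.na(f1), 0, f1) * support) / sum(support),
    macro_f1 = mean(f1[!is.na(f1)]),
    acc_exact = 100 * sum(tp, na.rm = TRUE) / sum(support)
  )
}

#' Spearman correlation between a feature and item scores
#'
#' @param feature numeric feature values.
#' @param scores item scores (ordinal).
#' @return list `r`, `p`, `band`; `r` is `NA` for a constant feature.
#' @export
feature_score_correlation <- function(feature, scores) {
  stopifnot(length(feature) == length(scores))
  if (length(feature) < 10L) stop("need n >= 10")
  if (stats::sd(feature, na.rm = TRUE) == 0)
    return(list(r = NA_real_, p = NA_real_, band = NA_character_))
  ct <- suppressWarnings(stats::cor.test(feature, scores, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value,
       band = correlation_band(unname(ct$estimate)))
}

#' Published reference per-class metrics and aggregates
#'
#' Loads the plain-text fixtures bundled with the package: the per-class
#' precision/recall/F1/support of the final item models of the original
#' 225-participant clinical study (LOOCV on 180 training and 45 independent
#' test participants) and the corresponding printed aggregate rows.
#'
#' @return list `per_class`, `aggregates` (data frames).
#' @export
reference_tables <- function() {
  pc <- utils::read.csv(system.file("extdata", "reference_item_metrics.csv",
                                    package = "gaitupdrs"),
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  ag <- utils::read.csv(system.file("extdata", "reference_item_aggregates.csv",
                                    package = "gaitupdrs"),
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  list(per_class = pc, aggregates = ag)
}

#' Reconstruct the published aggregate metrics from the per-class fixtures
#'
#' For every item and evaluation block (LOOCV / independent test), applies
#' [reconstruct_from_table()] to the published per-class precision, recall and
#' support and compares with the printed weighted F1, macro F1 and exact
#' accuracy.
#'
#' @return data frame with reconstructed and printed aggregates and absolute
#'   errors (`err_weighted_f1`, `err_macro_f1`, `err_acc0_pp`).
#' @export
verify_reference_tables <- function() {
  ref <- reference_tables()
  out <- list()
  for (it in unique(ref$per_class$item)) {
    for (bl in unique(ref$per_class$block)) {
      pc <- ref$per_class[ref$per_class$item == it & ref$per_class$block == bl, ]
      if (nrow(pc) == 0L) next
      rec <- reconstruct_from_table(pc$precision, pc$recall, pc$support)
      ag <- ref$aggregates[ref$aggregates$item == it &
                             ref$aggregates$block == bl, ]
      out[[length(out) + 1L]] <- data.frame(
        item = it, block = bl,
        weighted_f1 = rec$weighted_f1, weighted_f1_printed = ag$weighted_f1,
        macro_f1 = rec$macro_f1, macro_f1_printed = ag$macro_f1,
        acc0 = rec$acc_exact, acc0_printed = ag$acc0_pct,
        err_weighted_f1 = abs(rec$weighted_f1 - ag$weighted_f1),
        err_macro_f1 = abs(rec$macro_f1 - ag$macro_f1),
        err_acc0_pp = abs(rec$acc_exact - ag$acc0_pct)
      )
    }
  }
  do.call(rbind, out)
}
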