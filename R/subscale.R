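#' LASSO model for the gait and posture subscale
#'
#' The subscale is the sum of the five item scores (0-20). An L1-penalized
#' linear regression is fitted with the regularization constant chosen by
#' 10-fold cross-validation at the minimum mean cross-validated error; only
#' features with non-zero coefficients are kept.
#'
#' @param X training feature matrix (named columns; NAs median-imputed).
#' @param y subscale scores.
#' @param seed integer seed (fold assignment is deterministic given it).
#' @param nfolds cross-validation folds.
#' @return object of class `subscale_model`: `lambda`, `beta` (named non-zero
#'   coefficients), `intercept`, `features` (non-zero feature names),
#'   `medians`, and the fitted `cv.glmnet` object.
#' @export
fit_subscale <- function(X, y, seed = 1L, nfolds = 10) {
  X <- as.matrix(X)
  if (stats::sd(y) == 0) stop("degenerate subscale: y is constant")
  med <- col_medians(X)
  Xi <- impute_medians(X, med)
  cvfit <- with_seed(derive_seed(seed, "lasso"), {
    foldid <- sample(rep_len(seq_len(nfolds), nrow(Xi)))
    glmnet::cv.glmnet(Xi, y, alpha = 1, foldid = foldid)
  })
  co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
  nz <- co[-1L, 1L]
  nz <- nz[nz != 0]
  structure(list(lambda = cvfit$lambda.min, beta = nz,
                 intercept = co[1L, 1L], features = names(nz),
                 medians = med, cvfit = cvfit),
            class = "subscale_model")
}

#' @export
predict.subscale_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, names(object$medians), drop = FALSE])
  X <- impute_medians(X, object$medians)
  as.numeric(predict(object$cvfit, newx = X, s = "lambda.min"))
}
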