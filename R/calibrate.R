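#' Root mean square error
#'
#' @param predicted,observed equal-length numeric vectors (mg g^-1).
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(observed))
    stop("predicted and observed must be non-empty and of equal length")
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` about the observed mean; can be negative for predictions
#' worse than the mean.
#'
#' @inheritParams rmse
#' @return Dimensionless R-squared, `<= 1`.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(observed))
    stop("predicted and observed must be non-empty and of equal length")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed values have zero variance")
  1 - sum((observed - predicted)^2) / sst
}

#' Default hyperparameter grid for RBF support-vector regression
#'
#' Cost in `{1, 10, 100, 1000}`, kernel width `gamma` on a log grid
#' `2^-8..2^2`, epsilon in `{0.01, 0.1}`.
#'
#' @return A list with `cost`, `gamma`, `epsilon` vectors.
#' @export
default_svm_grid <- function() {
  list(cost = c(1, 10, 100, 1000), gamma = 2^seq(-8, 2, by = 1),
       epsilon = c(0.01, 0.1))
}

#' SVM regression on principal components
#'
#' Projects the calibration spectra onto their top principal components
#' (loadings fitted on the calibration data only) and fits an
#' epsilon-insensitive RBF support-vector regression on the scores.
#' Hyperparameters (cost, kernel width, epsilon) are chosen by seeded
#' fivefold cross-validated RMSE over the grid; when `n_pcs = NULL` the
#' component count minimizing that CV RMSE (up to `max_pcs`) is chosen
#' jointly. The reported `rmsecv` is the best fivefold CV RMSE, i.e. the same
#' partition used for tuning (an optimistic estimate, as no outer loop is
#' nested around the tuning).
#'
#' @param X calibration matrix (samples x channels).
#' @param y reference concentrations (mg g^-1).
#' @param n_pcs number of principal components, or `NULL` to choose by CV.
#' @param grid hyperparameter grid, see [default_svm_grid()].
#' @param seed integer seed for the fold assignment.
#' @param max_pcs cap on the component count searched when `n_pcs = NULL`.
#' @return An object of class `libs_svm` storing the centering vector, PCA
#'   rotation, fitted SVM, chosen hyperparameters and `rmsecv`.
#' @export
fit_svm_pcs <- function(X, y, n_pcs = NULL, grid = default_svm_grid(),
                        seed = 1, max_pcs = 13) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 6) stop("fivefold cross-validation needs at least 6 samples")
  if (!length(grid$cost) || !length(grid$gamma) || !length(grid$epsilon))
    stop("hyperparameter grid must be non-empty")
  rank_bound <- min(n - 1L, ncol(X))
  if (!is.null(n_pcs)) {
    if (n_pcs < 1 || n_pcs > rank_bound)
      stop("n_pcs must lie in 1..min(n-1, channels)")
  }
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  avail <- min(rank_bound, ncol(pca$rotation))
  pcs_try <- if (is.null(n_pcs)) seq_len(min(max_pcs, avail)) else n_pcs
  scores_all <- pca$x
  set.seed(seed)
  folds <- sample(rep_len(1:5, n))
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        epsilon = grid$epsilon, n_pcs = pcs_try,
                        KEEP.OUT.ATTRS = FALSE)
  cv_rmse <- vapply(seq_len(nrow(combos)), function(ci) {
    q <- combos$n_pcs[ci]
    S <- scores_all[, seq_len(q), drop = FALSE]
    press <- 0
    for (fold in 1:5) {
      hold <- folds == fold
      fit <- e1071::svm(S[!hold, , drop = FALSE], y[!hold],
                        type = "eps-regression", kernel = "radial",
                        cost = combos$cost[ci], gamma = combos$gamma[ci],
                        epsilon = combos$epsilon[ci])
      pr <- predict(fit, S[hold, , drop = FALSE])
      press <- press + sum((pr - y[hold])^2)
    }
    sqrt(press / n)
  }, numeric(1))
  best <- which.min(cv_rmse)
  q <- combos$n_pcs[best]
  S <- scores_all[, seq_len(q), drop = FALSE]
  final <- e1071::svm(S, y, type = "eps-regression", kernel = "radial",
                      cost = combos$cost[best], gamma = combos$gamma[best],
                      epsilon = combos$epsilon[best])
  structure(list(kind = "svm", center = pca$center,
                 rotation = pca$rotation[, seq_len(q), drop = FALSE],
                 n_pcs = q, model = final,
                 cost = combos$cost[best], gamma = combos$gamma[best],
                 epsilon = combos$epsilon[best],
                 rmsecv = cv_rmse[best], seed = seed, folds = folds),
            class = "libs_svm")
}

#' @export
predict.libs_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  S <- sweep(newdata, 2, object$center, "-") %*% object$rotation
  unname(predict(object$model, S))
}

#' @export
print.libs_svm <- function(x, ...) {
  cat("<libs_svm> RBF eps-regression on ", x$n_pcs, " PCs (cost=", x$cost,
      ", gamma=", format(x$gamma, digits = 3), ", epsilon=", x$epsilon,
      "); CV RMSE ", format(x$rmsecv, digits = 4), " mg/g\n", sep = "")
  invisible(x)
}

#' Evaluate a calibration model on calibration and prediction sets
#'
#' Computes the four figures of merit of a calibration study: R^2 and RMSECV
#' on the calibration set (RMSECV by the model's own cross-validation scheme:
#' leave-one-out for PLS and univariate models, the tuning fivefold partition
#' for SVM) and R^2 / RMSEP on the held-out prediction set.
#'
#' @param model a fitted `libs_pls`, `libs_svm` or `libs_univariate` model.
#' @param cal_X,cal_y calibration spectra (restricted to the model's
#'   channels) and concentrations.
#' @param pred_X,pred_y prediction-set spectra and concentrations.
#' @return An object of class `libs_metrics`: list with `r2_cal`, `rmsecv`,
#'   `r2_pred`, `rmsep`.
#' @export
evaluate <- function(model, cal_X, cal_y, pred_X, pred_y) {
  fit_cal <- predict(model, cal_X)
  fit_pred <- predict(model, pred_X)
  rmsecv <- if (inherits(model, "libs_svm")) {
    model$rmsecv
  } else if (inherits(model, "libs_pls")) {
    rc <- pls_rmsecv(as.matrix(cal_X), cal_y, model$n_lv)
    rc[length(rc)]
  } else if (!is.null(model$rmsecv)) {
    model$rmsecv
  } else {
    stop("model carries no cross-validation scheme")
  }
  structure(list(r2_cal = r_squared(fit_cal, cal_y),
                 rmsecv = rmsecv,
                 r2_pred = r_squared(fit_pred, pred_y),
                 rmsep = rmse(fit_pred, pred_y)),
            class = "libs_metrics")
}

#' @export
print.libs_metrics <- function(x, ...) {
  cat(sprintf("<libs_metrics> R2c %.4f | RMSECV %.3f | R2p %.4f | RMSEP %.3f (mg/g)\n",
              x$r2_cal, x$rmsecv, x$r2_pred, x$rmsep))
  invisible(x)
}
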