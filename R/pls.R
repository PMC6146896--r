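# Single-response PLS regression (SIMPLS, de Jong 1993) and leave-one-out
# cross-validation. This engine is called thousands of times by the interval
# selection algorithms, hence the lean matrix-only implementation.

# Fit SIMPLS with up to ncomp components. Returns coefficient matrix
# (p x a, one column per component count), intercepts, and the number of
# components actually extracted (fewer if X'y deflates to numerical zero).
simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2) stop("at least 2 samples are required")
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1) stop("ncomp must be >= 1 after the rank bound min(n-1, p)")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-")
  yc <- y - ym
  s <- crossprod(Xc, yc)
  s0 <- sqrt(sum(s^2))
  R <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  B <- matrix(0, p, ncomp)
  a <- 0L
  while (a < ncomp) {
    r <- s                                 # univariate: weight = deflated X'y
    if (sqrt(sum(r^2)) <= 1e-12 * max(s0, 1e-300)) break
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt <= 1e-300) break
    t <- t / nt; r <- r / nt
    pv <- crossprod(Xc, t)
    q <- sum(yc * t)
    v <- pv
    if (a > 0L)
      v <- v - V[, seq_len(a), drop = FALSE] %*%
        crossprod(V[, seq_len(a), drop = FALSE], pv)
    nv <- sqrt(sum(v^2))
    if (nv <= 1e-12 * max(sqrt(sum(pv^2)), 1e-300)) break
    v <- v / nv
    s <- s - v * drop(crossprod(v, s))
    a <- a + 1L
    R[, a] <- r; V[, a] <- v; Q[a] <- q
    B[, a] <- R[, seq_len(a), drop = FALSE] %*% Q[seq_len(a)]
  }
  B <- B[, seq_len(max(a, 1L)), drop = FALSE]
  if (a == 0L) B[] <- 0                    # degenerate: mean-only predictor
  icpt <- ym - drop(xm %*% B)
  list(coef = B, intercept = icpt, ncomp = a, xmeans = xm, ymean = ym)
}

# n x ncol(coef) matrix of predictions, one column per component count
simpls_predict <- function(fit, X) {
  X <- as.matrix(X)
  sweep(X %*% fit$coef, 2, fit$intercept, "+")
}

# Leave-one-out predictions for component counts 1..max_lv.
# If a left-out fit supports fewer components, the highest available
# prediction is carried forward (the model cannot grow further).
pls_loocv_predictions <- function(X, y, max_lv) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("leave-one-out PLS needs at least 3 samples")
  max_lv <- min(max_lv, n - 2L, ncol(X))
  if (max_lv < 1) stop("max_lv must be >= 1 after the rank bound")
  preds <- matrix(NA_real_, n, max_lv)
  ncomps <- integer(n)
  for (i in seq_len(n)) {
    fit <- simpls_fit(X[-i, , drop = FALSE], y[-i], max_lv)
    pr <- simpls_predict(fit, X[i, , drop = FALSE])
    k <- ncol(pr)
    preds[i, seq_len(k)] <- pr
    if (k < max_lv) preds[i, (k + 1L):max_lv] <- pr[, k]
    ncomps[i] <- fit$ncomp
  }
  structure(preds, ncomps = ncomps)
}

#' Leave-one-out RMSECV of a PLS model for each latent-variable count
#'
#' @param X calibration matrix (samples x channels).
#' @param y reference concentrations.
#' @param max_lv largest latent-variable count to evaluate; capped at
#'   `min(n - 2, ncol(X))`.
#' @return Numeric vector of RMSECV values (mg g^-1), one per LV count
#'   `1..max_lv` (after capping).
#' @export
pls_rmsecv <- function(X, y, max_lv) {
  preds <- pls_loocv_predictions(X, y, max_lv)
  apply(preds, 2, function(p) sqrt(mean((p - y)^2)))
}

#' Choose the PLS latent-variable count by leave-one-out cross-validation
#'
#' Evaluates LOO RMSECV for `1..max_lv` latent variables and returns the
#' count with the smallest RMSECV (ties broken toward fewer latent
#' variables).
#'
#' @inheritParams pls_rmsecv
#' @return List with `n_lv`, `rmsecv` (at the chosen count) and `rmsecv_all`.
#' @export
choose_lv_loocv <- function(X, y, max_lv) {
  rc <- pls_rmsecv(X, y, max_lv)
  best <- which.min(rc)                    # which.min takes the first minimum
  list(n_lv = best, rmsecv = rc[best], rmsecv_all = rc)
}

#' Fit a PLS calibration model
#'
#' Centered single-response partial least squares (SIMPLS). Predictions are
#' affine in the spectra.
#'
#' @param X calibration matrix (samples x channels).
#' @param y reference concentrations (mg g^-1).
#' @param n_lv number of latent variables, `<= min(n - 1, ncol(X))`.
#' @param channels optional channel indices the model applies to (metadata).
#' @return An object of class `libs_pls` with a [predict()][predict.libs_pls]
#'   method.
#' @export
fit_pls <- function(X, y, n_lv, channels = NULL) {
  X <- as.matrix(X)
  if (n_lv < 1 || n_lv > min(nrow(X) - 1L, ncol(X)))
    stop("n_lv must lie in 1..min(n-1, channels)")
  fit <- simpls_fit(X, y, n_lv)
  structure(list(kind = "pls", fit = fit, n_lv = n_lv,
                 requested_lv = n_lv, channels = channels),
            class = "libs_pls")
}

#' @export
predict.libs_pls <- function(object, newdata, ...) {
  pr <- simpls_predict(object$fit, newdata)
  pr[, ncol(pr)]
}

#' @export
print.libs_pls <- function(x, ...) {
  cat("<libs_pls> ", ncol(x$fit$coef), " latent variable(s), ",
      nrow(x$fit$coef), " channels\n", sep = "")
  invisible(x)
}
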