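# Successive projections algorithm: greedy selection of minimally collinear
# channels by orthogonal projection, plus prefix evaluation by leave-one-out
# multiple linear regression.

# center and unit-norm scale columns; near-zero-variance columns become 0
spa_preprocess <- function(X) {
  X <- as.matrix(X)
  Xc <- sweep(X, 2, colMeans(X), "-")
  nrm <- sqrt(colSums(Xc^2))
  keep <- nrm > 1e-12 * max(nrm, 1e-300)
  Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2, nrm[keep], "/")
  Xc[, !keep] <- 0
  Xc
}

#' Successive projections chain from one starting channel
#'
#' Columns are mean-centered and unit-norm scaled, then the chain grows
#' greedily: at each step every unselected column is projected onto the
#' orthogonal complement of the span of the selected columns (modified
#' Gram-Schmidt deflation) and the column with the largest residual norm is
#' added. Ties break toward the lowest column index; the chain stops early if
#' every residual is numerically zero (all remaining columns collinear with
#' the selection).
#'
#' @param X candidate matrix (samples x channels).
#' @param start starting column index.
#' @param p_max maximum chain length, `<= min(n - 1, ncol(X))`.
#' @return An object of class `libs_spa_chain`: list with `start`, `selected`
#'   (ordered column indices) and `proj_norms` (residual norm of each added
#'   column at its step; 1 for the normalized start).
#' @export
spa_chain <- function(X, start, p_max) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (start < 1 || start > m) stop("start column out of range")
  if (p_max < 1) stop("p_max must be >= 1")
  if (p_max > min(n - 1L, m))
    stop("p_max must not exceed min(n - 1, ncol(X))")
  Z <- spa_preprocess(X)
  if (sqrt(sum(Z[, start]^2)) <= 1e-12)
    stop("starting column has (near-)zero variance")
  selected <- integer(0)
  norms <- numeric(0)
  active <- rep(TRUE, m)
  R <- Z                                  # residuals after deflation
  pick <- as.integer(start)
  repeat {
    nrm <- sqrt(sum(R[, pick]^2))
    selected <- c(selected, pick)
    norms <- c(norms, nrm)
    active[pick] <- FALSE
    if (length(selected) >= p_max) break
    q <- R[, pick] / nrm
    R[, active] <- R[, active, drop = FALSE] -
      q %*% crossprod(q, R[, active, drop = FALSE])
    res <- colSums(R[, active, drop = FALSE]^2)
    if (!length(res) || max(res) <= 1e-20) break
    pick <- which(active)[which.max(res)] # first maximum: lowest index
  }
  structure(list(start = start, selected = selected, proj_norms = norms),
            class = "libs_spa_chain")
}

# leave-one-out RMSECV of OLS (with intercept) via the PRESS identity
# e_loo = e / (1 - h); falls back to explicit refits if any h ~ 1
ols_loocv_rmse <- function(X, y) {
  n <- nrow(X)
  A <- cbind(1, X)
  qrA <- qr(A)
  fit <- qr.coef(qrA, y)
  fit[is.na(fit)] <- 0
  res <- y - drop(A %*% fit)
  Q <- qr.Q(qrA)[, seq_len(qrA$rank), drop = FALSE]
  h <- rowSums(Q^2)
  if (any(h > 1 - 1e-10)) {
    press <- vapply(seq_len(n), function(i) {
      qi <- qr(A[-i, , drop = FALSE])
      b <- qr.coef(qi, y[-i]); b[is.na(b)] <- 0
      (y[i] - drop(A[i, ] %*% b))^2
    }, numeric(1))
    return(sqrt(mean(press)))
  }
  sqrt(mean((res / (1 - h))^2))
}

#' SPA variable selection over a candidate channel set
#'
#' Builds a [spa_chain()] from every candidate start, evaluates every chain
#' prefix (lengths `1..p_max`) by leave-one-out RMSECV of an ordinary
#' least-squares model on the calibration samples, and returns the prefix
#' with the smallest RMSECV. Ties break toward fewer channels, then the
#' earlier start.
#'
#' @param data calibration-set [spectral_dataset()].
#' @param candidates channel indices to select from (non-empty).
#' @param p_max maximum number of selected channels (default 30); capped at
#'   `min(n - 2, length(candidates))` so every prefix model is LOO-estimable.
#' @return A `libs_selection` with the chosen channels, `rmsecv`, the chain
#'   `start` channel and a `ledger` of (start, prefix length, RMSECV).
#' @export
spa_select <- function(data, candidates, p_max = 30) {
  stopifnot(inherits(data, "libs_dataset"))
  candidates <- sort(unique(as.integer(candidates)))
  if (!length(candidates)) stop("candidate set must be non-empty")
  X <- data$intensities[, candidates, drop = FALSE]
  y <- data$reference
  n <- nrow(X)
  if (n < 4) stop("at least 4 calibration samples are required")
  p_max <- min(p_max, n - 2L, ncol(X))
  if (p_max < 1) stop("p_max must be >= 1 after the sample bound")
  nrm <- sqrt(colSums(sweep(X, 2, colMeans(X), "-")^2))
  starts <- unname(which(nrm > 1e-12 * max(nrm, 1e-300)))
  if (!length(starts)) stop("all candidate channels are constant")
  rows <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    ch <- spa_chain(X, starts[si], p_max)
    rms <- vapply(seq_along(ch$selected), function(l)
      ols_loocv_rmse(X[, ch$selected[seq_len(l)], drop = FALSE], y),
      numeric(1))
    df <- data.frame(start = starts[si], length = seq_along(ch$selected),
                     rmsecv = rms)
    df$chain <- lapply(seq_along(ch$selected),
                       function(l) ch$selected[seq_len(l)])
    rows[[si]] <- df
  }
  ledger <- do.call(rbind, rows)
  # numerical-tie rule: prefixes whose RMSECV is within a relative epsilon of
  # the minimum count as ties, and the shortest (then earliest-start) wins --
  # otherwise floating noise below ~1e-12 would inflate exact-fit selections
  best_val <- min(ledger$rmsecv)
  tol <- max(1e-10, 1e-8 * best_val)
  tied <- ledger[ledger$rmsecv <= best_val + tol, ]
  best <- tied[order(tied$length, tied$start), ][1, ]
  local_channels <- best$chain[[1]]
  out <- selection_result("spa", data, candidates[local_channels],
                          rmsecv = best$rmsecv,
                          ledger = ledger[, c("start", "length", "rmsecv")])
  out$start <- candidates[best$start]
  out$order <- candidates[local_channels]   # selection order, unsorted
  out
}
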