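#' Equidistant partition of the channel axis
#'
#' Splits `p` channels into `k` contiguous intervals whose sizes differ by at
#' most one. The remainder channels are assigned to the leading intervals:
#' the first `p %% k` intervals have `ceiling(p / k)` channels, the rest
#' `floor(p / k)`. For 22,015 channels and 28 intervals this gives intervals
#' 1-7 of 787 channels and 8-28 of 786, the unique convention consistent with
#' the interval bookkeeping of backward elimination on a 22,015-channel axis.
#'
#' @param p total channel count.
#' @param k interval count, `1 <= k <= p`.
#' @return An object of class `interval_partition`: list with `p`, `k` and
#'   1-based inclusive `start` / `end` index vectors.
#' @examples
#' partition_equidistant(10, 3)            # sizes 4, 3, 3
#' interval_sizes(partition_equidistant(22015, 13))[8]   # 1693
#' @export
partition_equidistant <- function(p, k) {
  p <- as.integer(p); k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > p) stop("k must not exceed the channel count p")
  big <- p %% k                       # leading intervals take the remainder
  sizes <- rep(p %/% k, k)
  if (big > 0) sizes[seq_len(big)] <- sizes[seq_len(big)] + 1L
  ends <- cumsum(sizes)
  structure(list(p = p, k = k, start = c(1L, head(ends, -1L) + 1L),
                 end = ends),
            class = "interval_partition")
}

#' @rdname partition_equidistant
#' @param partition an `interval_partition`.
#' @export
interval_sizes <- function(partition) partition$end - partition$start + 1L

#' Channel indices of selected intervals
#'
#' @param partition an [partition_equidistant()] result.
#' @param which_intervals integer vector of interval indices (1-based).
#' @return Sorted integer vector of channel indices.
#' @export
interval_channels <- function(partition, which_intervals) {
  stopifnot(inherits(partition, "interval_partition"))
  if (any(which_intervals < 1 | which_intervals > partition$k))
    stop("interval index out of range")
  sort(unlist(lapply(sort(which_intervals), function(i)
    partition$start[i]:partition$end[i])))
}

#' @export
print.interval_partition <- function(x, ...) {
  cat("<interval_partition> ", x$p, " channels in ", x$k, " intervals (sizes ",
      max(interval_sizes(x)), "/", min(interval_sizes(x)), ")\n", sep = "")
  invisible(x)
}

#' Cross-validated PLS score of a channel subset
#'
#' Fits a PLS model on the given channels of the calibration data and returns
#' the leave-one-out RMSECV minimized over `1..max_lv` latent variables. When
#' the channels carry no usable covariance with the response (e.g. all
#' constant), the score falls back to the leave-one-out RMSE of the mean
#' predictor with `n_lv = 0`.
#'
#' @param data a [spectral_dataset()] (calibration samples only).
#' @param channels channel index vector, non-empty.
#' @param max_lv largest latent-variable count to try.
#' @return List with `rmsecv` (mg g^-1) and `n_lv`.
#' @export
interval_score <- function(data, channels, max_lv = 10) {
  stopifnot(inherits(data, "libs_dataset"))
  if (!length(channels)) stop("channel set must be non-empty")
  X <- data$intensities[, sort(channels), drop = FALSE]
  y <- data$reference
  preds <- pls_loocv_predictions(X, y, max_lv)
  rc <- apply(preds, 2, function(p) sqrt(mean((p - y)^2)))
  best <- which.min(rc)
  # degenerate case (e.g. all-constant channels): every left-out fit had
  # zero usable components and the score is that of the mean predictor
  if (all(attr(preds, "ncomps") == 0L)) list(rmsecv = rc[best], n_lv = 0L)
  else list(rmsecv = rc[best], n_lv = best)
}

#' Interval PLS (iPLS) variable selection
#'
#' For each interval count `k` in `k_range`, partitions the channel axis
#' equidistantly, scores a PLS model on every interval of the calibration
#' data by leave-one-out RMSECV, and returns the single interval with the
#' globally lowest score. Ties are broken toward smaller `k`, then lower
#' interval index.
#'
#' @param data calibration-set [spectral_dataset()].
#' @param k_range integer vector of interval counts to scan (default 2:30).
#' @param max_lv largest latent-variable count per interval model.
#' @return An object of class `libs_selection`: list with `method`,
#'   `channels`, `wavelength_ranges`, `k`, `intervals` (selected interval
#'   index), `rmsecv`, `n_lv` and a `ledger` data.frame of all candidate
#'   scores.
#' @export
ipls_select <- function(data, k_range = 2:30, max_lv = 10) {
  stopifnot(inherits(data, "libs_dataset"))
  if (!length(k_range)) stop("k_range must be non-empty")
  p <- length(data$wavelengths)
  rows <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    part <- partition_equidistant(p, k)
    for (i in seq_len(k)) {
      sc <- interval_score(data, part$start[i]:part$end[i], max_lv)
      rows[[length(rows) + 1L]] <-
        data.frame(k = k, interval = i, rmsecv = sc$rmsecv, n_lv = sc$n_lv)
    }
  }
  ledger <- do.call(rbind, rows)
  best <- ledger[order(ledger$rmsecv, ledger$k, ledger$interval), ][1, ]
  part <- partition_equidistant(p, best$k)
  channels <- interval_channels(part, best$interval)
  selection_result("ipls", data, channels,
                   k = best$k, intervals = best$interval,
                   rmsecv = best$rmsecv, n_lv = best$n_lv, ledger = ledger)
}

#' Backward interval PLS (BiPLS) elimination ledger
#'
#' Partitions the axis into `k` equidistant intervals and iteratively removes
#' the interval whose removal yields the lowest-RMSECV model among all
#' single-interval removals. Each ledger row records the state *before* that
#' row's removal: the number of intervals and channels remaining, the RMSECV
#' of the PLS model fitted on those remaining channels, and the interval then
#' removed. The final row is the last surviving interval.
#'
#' @param data calibration-set [spectral_dataset()].
#' @param k interval count, >= 2.
#' @param max_lv largest latent-variable count per model.
#' @return An object of class `libs_elimination`: list with `partition` and a
#'   `ledger` data.frame (`step`, `n_intervals`, `n_channels`, `rmsecv`,
#'   `n_lv`, `removed`, plus `remaining`, a list-column of the interval set
#'   each row's model used).
#' @export
bipls_eliminate <- function(data, k, max_lv = 10) {
  stopifnot(inherits(data, "libs_dataset"))
  if (k < 2) stop("k must be >= 2")
  p <- length(data$wavelengths)
  part <- partition_equidistant(p, k)
  remaining <- seq_len(k)
  cur <- interval_score(data, interval_channels(part, remaining), max_lv)
  rows <- list(); keep <- list()
  step <- 0L
  while (length(remaining) >= 1L) {
    step <- step + 1L
    if (length(remaining) == 1L) {
      removed <- remaining
    } else {
      cand <- vapply(remaining, function(r) {
        interval_score(data,
                       interval_channels(part, setdiff(remaining, r)),
                       max_lv)$rmsecv
      }, numeric(1))
      removed <- remaining[which.min(cand)]   # first minimum: lowest index
    }
    rows[[step]] <- data.frame(
      step = step, n_intervals = length(remaining),
      n_channels = length(interval_channels(part, remaining)),
      rmsecv = cur$rmsecv, n_lv = cur$n_lv, removed = removed)
    keep[[step]] <- remaining
    if (length(remaining) == 1L) break
    # the score of the surviving set is the winning removal's score
    nxt <- setdiff(remaining, removed)
    cur <- interval_score(data, interval_channels(part, nxt), max_lv)
    remaining <- nxt
  }
  ledger <- do.call(rbind, rows)
  ledger$remaining <- keep
  structure(list(partition = part, ledger = ledger),
            class = "libs_elimination")
}

#' @export
print.libs_elimination <- function(x, ...) {
  cat("<libs_elimination> k = ", x$partition$k, "; best step RMSECV ",
      format(min(x$ledger$rmsecv), digits = 4), " mg/g at ",
      x$ledger$n_channels[which.min(x$ledger$rmsecv)], " channels\n", sep = "")
  invisible(x)
}

#' Replay an elimination order through a partition (integer bookkeeping)
#'
#' Pure interval arithmetic with no model fitting: given a partition and an
#' ordered list of removed intervals, returns the channel count available to
#' each step's model (i.e. before that step's removal). Reproduces the
#' remaining-variable column of a backward-elimination ledger exactly.
#'
#' @param partition an [partition_equidistant()] result.
#' @param removed integer vector, the interval removed at each step; must be
#'   a permutation of `1:k`.
#' @return Integer vector of channel counts, one per step.
#' @examples
#' replay_elimination(partition_equidistant(10, 3), c(2, 3, 1))  # 10, 7, 4
#' @export
replay_elimination <- function(partition, removed) {
  stopifnot(inherits(partition, "interval_partition"))
  if (!setequal(removed, seq_len(partition$k)) ||
      length(removed) != partition$k)
    stop("removed must be a permutation of 1:k")
  sizes <- interval_sizes(partition)
  partition$p - c(0L, cumsum(sizes[removed])[-partition$k])
}

#' Backward interval PLS (BiPLS) variable selection
#'
#' Runs [bipls_eliminate()] for every interval count in `k_range`; within
#' each elimination ledger the step with minimal RMSECV defines that `k`'s
#' candidate interval set, and the candidate with the lowest RMSECV overall
#' is returned. Ties are broken toward fewer channels, then lower interval
#' count.
#'
#' @inheritParams ipls_select
#' @return A `libs_selection` (as in [ipls_select()]) whose `intervals` field
#'   holds the selected interval index set; the per-`k` elimination objects
#'   are attached as `eliminations`.
#' @export
bipls_select <- function(data, k_range = 2:30, max_lv = 10) {
  stopifnot(inherits(data, "libs_dataset"))
  if (!length(k_range)) stop("k_range must be non-empty")
  p <- length(data$wavelengths)
  elims <- list(); cands <- list()
  for (k in sort(unique(as.integer(k_range)))) {
    el <- bipls_eliminate(data, k, max_lv)
    led <- el$ledger
    i <- which.min(led$rmsecv)
    elims[[as.character(k)]] <- el
    cands[[length(cands) + 1L]] <- data.frame(
      k = k, rmsecv = led$rmsecv[i], n_lv = led$n_lv[i],
      n_channels = led$n_channels[i], step = led$step[i])
    cands[[length(cands)]]$remaining <- list(led$remaining[[i]])
  }
  cand <- do.call(rbind, cands)
  best <- cand[order(cand$rmsecv, cand$n_channels, cand$k), ][1, ]
  part <- partition_equidistant(p, best$k)
  intervals <- best$remaining[[1]]
  channels <- interval_channels(part, intervals)
  out <- selection_result("bipls", data, channels,
                          k = best$k, intervals = intervals,
                          rmsecv = best$rmsecv, n_lv = best$n_lv,
                          ledger = cand[, c("k", "step", "n_channels",
                                            "rmsecv", "n_lv")])
  out$eliminations <- elims
  out
}

# common constructor: derive wavelength ranges from contiguous channel runs
selection_result <- function(method, data, channels, k = NA, intervals = NULL,
                             rmsecv = NA, n_lv = NA, ledger = NULL,
                             extra = NULL) {
  channels <- sort(unique(as.integer(channels)))
  p <- length(data$wavelengths)
  if (!length(channels) || any(channels < 1 | channels > p))
    stop("selected channels must be a non-empty subset of 1..p")
  runs <- split(channels, cumsum(c(1L, diff(channels) != 1L)))
  ranges <- data.frame(
    min_nm = vapply(runs, function(r) data$wavelengths[min(r)], numeric(1)),
    max_nm = vapply(runs, function(r) data$wavelengths[max(r)], numeric(1)),
    n_channels = lengths(runs), row.names = NULL)
  out <- list(method = method, channels = channels,
              wavelength_ranges = ranges, k = k, intervals = intervals,
              rmsecv = rmsecv, n_lv = n_lv, ledger = ledger)
  structure(c(out, extra), class = "libs_selection")
}

#' @export
print.libs_selection <- function(x, ...) {
  cat("<libs_selection> ", x$method, ": ", length(x$channels),
      " channels, RMSECV ", format(x$rmsecv, digits = 4), " mg/g\n", sep = "")
  rr <- x$wavelength_ranges
  cat("  ranges: ", paste(sprintf("%.2f-%.2f nm", rr$min_nm, rr$max_nm),
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a selection result (channel indices and wavelength ranges)
#'
#' @param selection a `libs_selection`.
#' @param path base file path; `<path>_channels.tsv` and `<path>_ranges.tsv`
#'   are written.
#' @export
write_selection <- function(selection, path) {
  stopifnot(inherits(selection, "libs_selection"))
  data.table::fwrite(data.table::data.table(channel = selection$channels),
                     paste0(path, "_channels.tsv"), sep = "\t")
  data.table::fwrite(selection$wavelength_ranges,
                     paste0(path, "_ranges.tsv"), sep = "\t")
  invisible(path)
}

#' Write a BiPLS elimination ledger as delimited text
#'
#' Columns mirror a backward-elimination report: step, removed interval,
#' RMSECV of the step's model, and the channel count that model used.
#'
#' @param elimination a [bipls_eliminate()] result.
#' @param path file path.
#' @export
write_ledger <- function(elimination, path) {
  stopifnot(inherits(elimination, "libs_elimination"))
  led <- elimination$ledger
  data.table::fwrite(led[, c("step", "removed", "rmsecv", "n_channels")],
                     path, sep = "\t")
  invisible(path)
}
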