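# Orthogonal Daubechies-6 (12-tap) discrete wavelet transform with
# periodization, plus soft-threshold denoising. Implemented here because the
# transform sits on the preprocessing critical path of the pipeline.

# db6 scaling (low-pass) filter, sum = sqrt(2), sum of squares = 1
DB6_LO <- c(0.111540743350109470, 0.494623890398453060, 0.751133908021095400,
            0.315250351709197630, -0.226264693965439830, -0.129766867567261940,
            0.097501605587323040, 0.027522865530305727, -0.031582039317486030,
            0.000553842201161496, 0.004777257510945511, -0.001077301085308480)

qmf_hi <- function(lo) rev(lo) * (-1)^(seq_along(lo) - 1)

# one periodized analysis step; length(x) must be even
dwt_step <- function(x, lo, hi) {
  n <- length(x)
  half <- n %/% 2L
  a <- numeric(half)
  d <- numeric(half)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(lo)) {
    idx <- (base + (j - 1L)) %% n + 1L
    a <- a + lo[j] * x[idx]
    d <- d + hi[j] * x[idx]
  }
  list(a = a, d = d)
}

# exact inverse of dwt_step (transpose of the orthogonal analysis operator)
idwt_step <- function(a, d, lo, hi) {
  half <- length(a)
  n <- 2L * half
  x <- numeric(n)
  base <- 2L * (seq_len(half) - 1L)
  for (j in seq_along(lo)) {
    idx <- (base + (j - 1L)) %% n + 1L
    x[idx] <- x[idx] + lo[j] * a + hi[j] * d
  }
  x
}

# multi-level periodized DWT; returns approximation + list of detail vectors
dwt_multilevel <- function(x, level, lo = DB6_LO) {
  hi <- qmf_hi(lo)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwt_step(a, lo, hi)
    a <- s$a
    details[[l]] <- s$d
  }
  list(a = a, d = details)
}

idwt_multilevel <- function(w, lo = DB6_LO) {
  hi <- qmf_hi(lo)
  a <- w$a
  for (l in rev(seq_along(w$d)))
    a <- idwt_step(a, w$d[[l]], lo, hi)
  a
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Wavelet denoising of a spectrum
#'
#' Multi-level Daubechies-6 wavelet decomposition, soft thresholding of the
#' detail coefficients, and reconstruction. The threshold at each level is the
#' universal threshold `sigma * sqrt(2 * log(n))` with `sigma` estimated from
#' that level's detail coefficients by the median absolute deviation
#' (`MAD / 0.6745`). Signals are padded by symmetric reflection to a length
#' divisible by `2^level` (at least one filter length per side) and the
#' transform is periodized on the padded signal, so reconstruction is exact
#' and boundary artifacts are confined to the discarded pad.
#'
#' @param x numeric intensity sequence.
#' @param level decomposition depth (default 3).
#' @param threshold `"universal"` (default) or a fixed non-negative number
#'   applied to all detail levels.
#' @return Denoised sequence of the same length as `x`.
#' @examples
#' set.seed(1)
#' x <- sin(seq(0, 4 * pi, length.out = 256)) + rnorm(256, sd = 0.2)
#' sd(wavelet_denoise(x) - sin(seq(0, 4 * pi, length.out = 256)))
#' @export
wavelet_denoise <- function(x, level = 3, threshold = "universal") {
  n <- length(x)
  L <- length(DB6_LO)
  if (level < 1) stop("level must be >= 1")
  if (n < 2L * L) stop("signal too short for the db6 filter support")
  block <- 2L^level
  pad <- L * block             # generous symmetric pad on each side
  # reflect (edge-repeating); tile if the signal is shorter than the pad
  left <- rev(rep_len(x, pad))          # ..., x[2], x[1] | x[1], x[2], ...
  right <- rep_len(rev(x), pad)         # ..., x[n] | x[n], x[n-1], ...
  total <- n + 2L * pad
  extra <- (block - total %% block) %% block
  right <- c(right, rep(right[length(right)], extra))
  xe <- c(left, x, right)
  if (2L^level > length(xe))
    stop("decomposition level too deep for signal length")
  w <- dwt_multilevel(xe, level)
  for (l in seq_len(level)) {
    d <- w$d[[l]]
    thr <- if (identical(threshold, "universal")) {
      sigma <- median(abs(d)) / 0.6745
      sigma * sqrt(2 * log(length(xe)))
    } else {
      if (!is.numeric(threshold) || threshold < 0)
        stop("threshold must be \"universal\" or a non-negative number")
      threshold
    }
    w$d[[l]] <- soft_threshold(d, thr)
  }
  idwt_multilevel(w)[pad + seq_len(n)]
}

#' Denoise every spectrum of a dataset
#'
#' Applies [wavelet_denoise()] row-wise; wavelengths, reference values and ids
#' are unchanged. Denoising is strictly per-sample, so prediction-set spectra
#' never influence calibration-set preprocessing.
#'
#' @param data a [spectral_dataset()].
#' @inheritParams wavelet_denoise
#' @return A `libs_dataset` of identical shape.
#' @export
denoise_dataset <- function(data, level = 3, threshold = "universal") {
  stopifnot(inherits(data, "libs_dataset"))
  out <- t(apply(data$intensities, 1, wavelet_denoise,
                 level = level, threshold = threshold))
  spectral_dataset(data$wavelengths, out, data$reference, data$ids)
}
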