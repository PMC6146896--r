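#' Extract an emission-line intensity from a spectrum
#'
#' `mode = "nearest"` returns the intensity at the channel whose wavelength is
#' closest to `line_nm` (the default: each channel is treated as one
#' variable); `mode = "window_max"` returns the maximum intensity within
#' `line_nm +- window`, which tolerates small wavelength-registration offsets.
#'
#' @param wavelengths wavelength axis (nm) or a `libs_spectrum`.
#' @param intensities intensity vector (omit when a `libs_spectrum` is given).
#' @param line_nm line position (nm); must lie within the axis range.
#' @param mode `"nearest"` or `"window_max"`.
#' @param window half-width (nm) for `window_max`.
#' @return A single intensity value.
#' @export
line_intensity <- function(wavelengths, intensities = NULL, line_nm,
                           mode = c("nearest", "window_max"), window = 0.1) {
  if (inherits(wavelengths, "libs_spectrum")) {
    intensities <- wavelengths$intensities
    wavelengths <- wavelengths$wavelengths
  }
  mode <- match.arg(mode)
  if (line_nm < min(wavelengths) || line_nm > max(wavelengths))
    stop("line_nm lies outside the wavelength axis")
  if (mode == "nearest")
    return(intensities[which.min(abs(wavelengths - line_nm))])
  inwin <- abs(wavelengths - line_nm) <= window
  if (!any(inwin))
    return(intensities[which.min(abs(wavelengths - line_nm))])
  max(intensities[inwin])
}

#' Per-sample line intensities from a dataset
#'
#' Vectorized [line_intensity()] across all samples of a dataset.
#'
#' @param data a [spectral_dataset()].
#' @inheritParams line_intensity
#' @return Numeric vector, one intensity per sample.
#' @export
extract_line <- function(data, line_nm, mode = c("nearest", "window_max"),
                         window = 0.1) {
  stopifnot(inherits(data, "libs_dataset"))
  mode <- match.arg(mode)
  if (line_nm < min(data$wavelengths) || line_nm > max(data$wavelengths))
    stop("line_nm lies outside the wavelength axis")
  if (mode == "nearest") {
    ch <- which.min(abs(data$wavelengths - line_nm))
    return(data$intensities[, ch])
  }
  inwin <- abs(data$wavelengths - line_nm) <= window
  if (!any(inwin)) inwin <- which.min(abs(data$wavelengths - line_nm))
  apply(data$intensities[, inwin, drop = FALSE], 1, max)
}

#' Cd intensity-ratio indices
#'
#' Internal-standardization indices built from the Cd I lines at 508.58 nm
#' and 361.05 nm (concentration-sensitive) and 466.23 nm (background-like,
#' tracking the shared shot factor): `index1 = (i508 + i361) / (2 * i466)`
#' and `index2 = i508 / i466`. Because the shot factor multiplies all line
#' intensities of a spectrum alike, it cancels in the ratio.
#'
#' @param i508,i361,i466 line intensities (vectors recycle as usual).
#' @return Dimensionless index values.
#' @examples
#' index1(2, 4, 2)   # 1.5
#' index2(3, 1.5)    # 2
#' @export
index1 <- function(i508, i361, i466) {
  if (any(i466 <= 0)) stop("denominator intensity i466 must be > 0")
  (i508 + i361) / (2 * i466)
}

#' @rdname index1
#' @export
index2 <- function(i508, i466) {
  if (any(i466 <= 0)) stop("denominator intensity i466 must be > 0")
  i508 / i466
}

#' Univariate calibration from a per-sample scalar predictor
#'
#' Ordinary least-squares line `concentration = a * predictor + b`, fitted on
#' the calibration samples of the split. RMSECV is computed by leave-one-out
#' cross-validation (via the PRESS identity); R^2 and RMSEP are evaluated on
#' the prediction samples.
#'
#' @param predictor numeric vector, one scalar per sample (a line intensity
#'   or index value).
#' @param reference reference concentrations (mg g^-1), same length.
#' @param split a [split_rank_ordered()] result over the same samples.
#' @return A list of class `libs_univariate`: `slope`, `intercept`,
#'   `rmsecv`, and `metrics` (a `libs_metrics`). The object has a
#'   [predict()][predict.libs_univariate] method.
#' @export
fit_univariate <- function(predictor, reference, split) {
  stopifnot(inherits(split, "libs_split"))
  if (length(predictor) != length(reference))
    stop("predictor and reference must have equal length")
  xc <- predictor[split$calibration]
  yc <- reference[split$calibration]
  if (length(xc) < 3) stop("at least 3 calibration samples are required")
  if (var(xc) <= 0) stop("predictor has zero variance on the calibration set")
  b <- cov(xc, yc) / var(xc)
  a <- mean(yc) - b * mean(xc)
  # LOO via PRESS on the two-parameter fit
  A <- cbind(1, xc)
  qrA <- qr(A)
  res <- yc - drop(A %*% qr.coef(qrA, yc))
  h <- rowSums(qr.Q(qrA)[, 1:2, drop = FALSE]^2)
  rmsecv <- sqrt(mean((res / (1 - h))^2))
  model <- structure(list(kind = "univariate", slope = b, intercept = a,
                          rmsecv = rmsecv),
                     class = "libs_univariate")
  metrics <- evaluate(model, xc, yc,
                      predictor[split$prediction], reference[split$prediction])
  model$metrics <- metrics
  model
}

#' @export
predict.libs_univariate <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
print.libs_univariate <- function(x, ...) {
  cat(sprintf("<libs_univariate> conc = %.4g * x + %.4g\n", x$slope, x$intercept))
  print(x$metrics)
  invisible(x)
}

#' Restrict a line catalog to wavelength ranges
#'
#' Keeps the catalog entries whose center falls inside any of the given
#' closed wavelength intervals (endpoints included).
#'
#' @param catalog a data.frame with a `center` column (nm), e.g.
#'   [default_line_catalog()].
#' @param ranges data.frame or matrix with two columns (min, max) in nm; may
#'   have zero rows.
#' @return The catalog subset (possibly empty).
#' @export
lines_in_ranges <- function(catalog, ranges) {
  ranges <- as.matrix(as.data.frame(ranges))
  if (!nrow(ranges)) return(catalog[0, , drop = FALSE])
  hit <- vapply(catalog$center, function(nm)
    any(nm >= ranges[, 1] & nm <= ranges[, 2]), logical(1))
  catalog[hit, , drop = FALSE]
}

#' Univariate calibration table over catalogued lines
#'
#' Fits [fit_univariate()] for every line of the catalog on its extracted
#' per-sample intensity and returns one row of figures of merit per line.
#'
#' @param data a (denoised) [spectral_dataset()].
#' @param split a [split_rank_ordered()] result.
#' @param catalog line catalog (defaults to the Cd lines of
#'   [default_line_catalog()]).
#' @param mode,window see [line_intensity()].
#' @return data.frame with columns `element`, `line_nm`, `r2_cal`, `rmsecv`,
#'   `r2_pred`, `rmsep`.
#' @export
univariate_table <- function(data, split, catalog = NULL,
                             mode = "nearest", window = 0.1) {
  stopifnot(inherits(data, "libs_dataset"))
  if (is.null(catalog)) {
    catalog <- default_line_catalog()
    catalog <- catalog[catalog$element == "Cd", ]
  }
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    x <- extract_line(data, catalog$center[i], mode, window)
    fit <- fit_univariate(x, data$reference, split)
    m <- fit$metrics
    data.frame(element = catalog$element[i], line_nm = catalog$center[i],
               r2_cal = m$r2_cal, rmsecv = m$rmsecv,
               r2_pred = m$r2_pred, rmsep = m$rmsep)
  })
  do.call(rbind, rows)
}
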