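#' Spectral dataset container
#'
#' Bundles an intensity matrix with its wavelength axis, per-sample reference
#' concentrations and sample identifiers. This is the object every stage of
#' the pipeline consumes and returns.
#'
#' @param wavelengths numeric vector of strictly increasing wavelengths (nm),
#'   one per channel.
#' @param intensities numeric matrix, samples in rows, channels in columns.
#' @param reference numeric vector of reference analyte concentrations
#'   (mg g^-1), one per sample; must be non-negative.
#' @param ids character vector of sample identifiers (defaults to
#'   `"s1", "s2", ...`).
#'
#' @return An object of class `libs_dataset`: a list with elements
#'   `wavelengths`, `intensities`, `reference`, `ids`.
#' @examples
#' d <- spectral_dataset(c(400, 500, 600),
#'                       matrix(1:6, nrow = 2, byrow = TRUE),
#'                       reference = c(0.5, 1.2))
#' d
#' @export
spectral_dataset <- function(wavelengths, intensities, reference,
                             ids = paste0("s", seq_len(nrow(intensities)))) {
  wavelengths <- as.numeric(wavelengths)
  if (!is.matrix(intensities)) intensities <- rbind(intensities)
  storage.mode(intensities) <- "double"
  reference <- as.numeric(reference)
  ids <- as.character(ids)
  if (ncol(intensities) != length(wavelengths))
    stop("intensity columns (", ncol(intensities),
         ") must match wavelength axis length (", length(wavelengths), ")")
  if (nrow(intensities) != length(reference))
    stop("one reference concentration per sample is required")
  if (nrow(intensities) != length(ids))
    stop("one id per sample is required")
  if (length(wavelengths) >= 2 && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(reference)) || any(reference < 0))
    stop("reference concentrations must be finite and >= 0")
  rownames(intensities) <- ids
  structure(list(wavelengths = wavelengths, intensities = intensities,
                 reference = reference, ids = ids),
            class = "libs_dataset")
}

#' @export
print.libs_dataset <- function(x, ...) {
  cat("<libs_dataset> ", nrow(x$intensities), " samples x ",
      length(x$wavelengths), " channels (",
      format(min(x$wavelengths)), "-", format(max(x$wavelengths)), " nm)\n",
      sep = "")
  cat("  reference Cd: ", format(min(x$reference), digits = 4), "-",
      format(max(x$reference), digits = 4), " mg/g\n", sep = "")
  invisible(x)
}

#' @export
dim.libs_dataset <- function(x) dim(x$intensities)

#' Subset a spectral dataset by samples and/or channels
#'
#' @param data a [spectral_dataset()].
#' @param samples integer or logical index of samples to keep (default all).
#' @param channels integer or logical index of channels to keep (default all).
#' @return A `libs_dataset` restricted to the requested rows/columns.
#' @export
subset_dataset <- function(data, samples = NULL, channels = NULL) {
  stopifnot(inherits(data, "libs_dataset"))
  if (is.null(samples)) samples <- seq_along(data$ids)
  if (is.null(channels)) channels <- seq_along(data$wavelengths)
  spectral_dataset(data$wavelengths[channels],
                   data$intensities[samples, channels, drop = FALSE],
                   data$reference[samples],
                   data$ids[samples])
}

#' Read / write spectral datasets as delimited text
#'
#' The on-disk layout is one header row holding the wavelength axis and one
#' row per sample: column 1 the sample id, column 2 the reference
#' concentration (mg g^-1), remaining columns the intensities. Tab-separated,
#' UTF-8, `.` decimal separator.
#'
#' @param data a [spectral_dataset()].
#' @param path file path.
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a `libs_dataset`.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "libs_dataset"))
  dt <- data.table::data.table(id = data$ids, reference = data$reference)
  mat <- data.table::as.data.table(data$intensities)
  data.table::setnames(mat, format(data$wavelengths, trim = TRUE, digits = 15))
  data.table::fwrite(cbind(dt, mat), path, sep = "\t")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 3) stop("dataset file needs id, reference and >=1 channel")
  wl <- as.numeric(names(dt)[-(1:2)])
  if (any(is.na(wl))) stop("header row must hold numeric wavelengths")
  spectral_dataset(wl, as.matrix(dt[, -(1:2)]), dt[[2]], dt[[1]])
}
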