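#' Default emission-line catalog for tobacco-root LIBS spectra
#'
#' The line identities follow the strong lines observed in tobacco-root LIBS
#' spectra: ten Cd I analyte lines, the major matrix-element lines (C, Mg, Ca,
#' Cu, CN, Na, K), and the Fe I 360.88 nm line adjacent to Cd I 361.05 nm,
#' flagged as an interferent. Cd I 466.23 nm is configured background-like
#' (zero concentration sensitivity, fixed base intensity) so its intensity
#' tracks the shot-to-shot factor rather than Cd content, which is the
#' mechanism the ratio indices exploit.
#'
#' Columns: `element`, `center` (nm), `width` (FWHM, nm), `sensitivity`
#' (intensity units per mg g^-1 for analyte lines; fixed base intensity for
#' matrix / interferent / background lines) and `kind` (one of `"analyte"`,
#' `"matrix"`, `"interferent"`, `"background"`).
#'
#' @return A data.frame of class `libs_line_catalog`.
#' @export
default_line_catalog <- function() {
  cat <- rbind(
    # -- Cd analyte lines; sensitivities reflect relative line strengths,
    #    with 508.58 nm the strongest interference-free line
    data.frame(element = "Cd",
               center = c(326.10, 340.36, 346.61, 361.05, 361.28,
                          361.44, 467.81, 508.58, 643.84),
               sensitivity = c(60, 45, 55, 100, 35, 15, 30, 150, 10),
               kind = "analyte"),
    # background-like Cd line: no usable correlation with Cd content
    data.frame(element = "Cd", center = 466.23, sensitivity = 120,
               kind = "background"),
    data.frame(element = "Fe", center = 360.88, sensitivity = 400,
               kind = "interferent"),
    data.frame(element = c("C", "Mg", "Mg", "Mg", "Mg",
                           "Ca", "Ca", "Ca", "Ca", "Ca", "Ca", "Ca", "Ca",
                           "Cu", "Cu", "CN", "CN", "Na", "Na", "K", "K"),
               center = c(247.86, 279.55, 279.80, 383.82, 516.73,
                          373.69, 397.37, 422.67, 558.90, 643.91, 644.98,
                          849.80, 866.21,
                          324.75, 327.40, 393.37, 396.85,
                          589.00, 589.59, 766.49, 769.90),
               sensitivity = c(500, 450, 420, 380, 300,
                               350, 320, 300, 280, 200, 200, 150, 150,
                               250, 230, 300, 280, 400, 380, 350, 330),
               kind = "matrix")
  )
  cat$width <- 0.1
  cat <- cat[, c("element", "center", "width", "sensitivity", "kind")]
  validate_line_catalog(cat)
}

validate_line_catalog <- function(cat) {
  need <- c("element", "center", "width", "sensitivity", "kind")
  if (!all(need %in% names(cat)))
    stop("line catalog needs columns: ", paste(need, collapse = ", "))
  if (any(cat$width <= 0)) stop("line widths must be > 0")
  if (any(cat$sensitivity < 0)) stop("line sensitivities must be >= 0")
  if (any(cat$center <= 0)) stop("line centers must be positive wavelengths")
  ok <- c("analyte", "matrix", "interferent", "background")
  if (!all(cat$kind %in% ok))
    stop("line kind must be one of: ", paste(ok, collapse = ", "))
  if (anyDuplicated(cat[, c("element", "center")]))
    stop("line catalog entries must be unique by (element, center)")
  class(cat) <- c("libs_line_catalog", "data.frame")
  cat
}

#' Read / write an emission-line catalog
#'
#' Delimited text with columns element, center, width, sensitivity, kind.
#'
#' @param catalog a line catalog data.frame (see [default_line_catalog()]).
#' @param path file path.
#' @export
write_line_catalog <- function(catalog, path) {
  data.table::fwrite(validate_line_catalog(catalog), path, sep = "\t")
  invisible(path)
}

#' @rdname write_line_catalog
#' @export
read_line_catalog <- function(path) {
  validate_line_catalog(as.data.frame(data.table::fread(path, sep = "\t")))
}

#' Simulation configuration
#'
#' Describes the study design a synthetic dataset emulates: the five Cd-stress
#' groups (sizes, truncated-normal concentration means/SDs per the reference
#' ICP-OES measurements), the wavelength axis, the emission-line catalog, the
#' noise model, and the per-sample replicate count.
#'
#' Noise model: per replicate shot, all line intensities share one
#' multiplicative lognormal factor `f` (`shot_sigma` is the lognormal sdlog;
#' `meanlog = -shot_sigma^2/2` so `E[f] = 1`), and independent additive
#' Gaussian noise of standard deviation `noise_sd` is added per channel.
#' Matrix-line heights optionally drift upward with Cd content
#' (`matrix_trend`, relative slope per mg g^-1), echoing the increase of
#' matrix-line intensity with Cd stress seen in real spectra.
#'
#' @param n_per_group integer vector, samples per concentration group.
#' @param group_means,group_sds numeric vectors (mg g^-1), truncated-normal
#'   parameters of each group's Cd content.
#' @param axis_min,axis_max,n_channels wavelength axis specification (nm).
#' @param catalog emission-line catalog (see [default_line_catalog()]).
#' @param shot_sigma lognormal sdlog of the shared multiplicative shot factor.
#' @param noise_sd additive channel-noise standard deviation (intensity units).
#' @param baseline numeric polynomial coefficients (intercept first) of a
#'   baseline evaluated on the wavelength axis scaled to `[0, 1]`; default a
#'   flat zero baseline.
#' @param matrix_trend relative increase of matrix-line height per mg g^-1 Cd.
#' @param replicates shots averaged into one recorded spectrum per sample.
#' @param eta Lorentzian fraction of the pseudo-Voigt line profile.
#' @param seed integer seed making [simulate_dataset()] reproducible.
#' @return An object of class `libs_sim_config`.
#' @export
simulation_config <- function(n_per_group = c(12, 12, 18, 18, 18),
                              group_means = c(0.001, 0.015, 2.304, 6.663, 11.577),
                              group_sds = c(0.006, 0.087, 0.602, 1.735, 2.617),
                              axis_min = 229.99, axis_max = 880.01,
                              n_channels = 22015,
                              catalog = default_line_catalog(),
                              shot_sigma = 0.2, noise_sd = 1,
                              baseline = 0, matrix_trend = 0.02,
                              replicates = 80, eta = 0.3, seed = NULL) {
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) == 0L || any(n_per_group < 1L))
    stop("every concentration group must contain at least one sample")
  if (length(group_means) != length(n_per_group) ||
      length(group_sds) != length(n_per_group))
    stop("group_means and group_sds must match n_per_group in length")
  if (any(group_means < 0)) stop("group means must be >= 0")
  if (any(group_sds < 0) || shot_sigma < 0 || noise_sd < 0)
    stop("spreads must be >= 0")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (axis_max <= axis_min) stop("axis_max must exceed axis_min")
  if (replicates < 1) stop("replicates must be >= 1")
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  catalog <- validate_line_catalog(as.data.frame(catalog))
  if (any(catalog$center < axis_min | catalog$center > axis_max))
    stop("all catalogued line centers must lie within the wavelength axis")
  structure(list(n_per_group = n_per_group, group_means = group_means,
                 group_sds = group_sds, axis_min = axis_min,
                 axis_max = axis_max, n_channels = as.integer(n_channels),
                 catalog = catalog, shot_sigma = shot_sigma,
                 noise_sd = noise_sd, baseline = baseline,
                 matrix_trend = matrix_trend,
                 replicates = as.integer(replicates), eta = eta, seed = seed),
            class = "libs_sim_config")
}

#' @export
print.libs_sim_config <- function(x, ...) {
  cat("<libs_sim_config> ", sum(x$n_per_group), " samples in ",
      length(x$n_per_group), " groups; axis ", x$axis_min, "-", x$axis_max,
      " nm x ", x$n_channels, " channels\n", sep = "")
  cat("  ", nrow(x$catalog), " lines; shot_sigma=", x$shot_sigma,
      " noise_sd=", x$noise_sd, " replicates=", x$replicates, "\n", sep = "")
  invisible(x)
}

#' Read / write a simulation configuration as a flat key-value (YAML) file
#'
#' Scalar fields are stored as keys; the line catalog is stored in a separate
#' delimited file referenced by the `catalog` key (written next to `path` as
#' `<path>_catalog.tsv` by `write_sim_config()` unless `catalog_path` is
#' given).
#'
#' @param config a [simulation_config()].
#' @param path YAML file path.
#' @param catalog_path where to write the line catalog.
#' @export
write_sim_config <- function(config, path,
                             catalog_path = paste0(path, "_catalog.tsv")) {
  stopifnot(inherits(config, "libs_sim_config"))
  write_line_catalog(config$catalog, catalog_path)
  flat <- config[setdiff(names(config), "catalog")]
  flat$catalog <- catalog_path
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  flat <- yaml::read_yaml(path)
  catalog <- read_line_catalog(flat$catalog)
  flat$catalog <- catalog
  do.call(simulation_config, flat)
}

#' Build a uniform wavelength axis
#'
#' @param min_nm,max_nm axis endpoints (nm), `max_nm > min_nm`.
#' @param n_channels number of channels, at least 2.
#' @return Strictly increasing, uniformly spaced numeric vector whose first
#'   and last elements equal the endpoints.
#' @examples
#' a <- build_axis(229.99, 880.01, 22015)
#' diff(a)[1]   # ~0.02954 nm
#' @export
build_axis <- function(min_nm, max_nm, n_channels) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (max_nm <= min_nm) stop("max_nm must exceed min_nm")
  seq(min_nm, max_nm, length.out = n_channels)
}

#' Pseudo-Voigt emission-line profile on a wavelength axis
#'
#' A convex mix of a Lorentzian (fraction `eta`) and a Gaussian sharing the
#' same full width at half maximum. The profile is rescaled so the channel
#' nearest `center` carries exactly `height`, making peak heights exact on
#' arbitrary grids.
#'
#' @param center line center (nm).
#' @param width full width at half maximum (nm), > 0.
#' @param height peak intensity at the channel nearest `center`.
#' @param axis wavelength axis (nm).
#' @param eta Lorentzian fraction in `[0, 1]`; `eta = 0` is pure Gaussian.
#' @return Numeric vector of intensities along `axis`.
#' @export
line_profile <- function(center, width, height, axis, eta = 0.3) {
  if (width <= 0) stop("width must be > 0")
  if (height == 0) return(numeric(length(axis)))
  shape <- pseudo_voigt(axis - center, width, eta)
  near <- which.min(abs(axis - center))
  height * shape / shape[near]
}

# unnormalized pseudo-Voigt: unit maximum at delta = 0
pseudo_voigt <- function(delta, fwhm, eta) {
  g <- exp(-4 * log(2) * (delta / fwhm)^2)
  l <- 1 / (1 + (2 * delta / fwhm)^2)
  eta * l + (1 - eta) * g
}

# Sum of all catalogued line profiles at Cd concentration cd (no noise, f = 1).
# Profiles are only evaluated within +-8 FWHM of each center for speed.
line_sum <- function(config, cd) {
  axis <- build_axis(config$axis_min, config$axis_max, config$n_channels)
  out <- numeric(length(axis))
  cat <- config$catalog
  for (i in seq_len(nrow(cat))) {
    h <- switch(cat$kind[i],
                analyte = cat$sensitivity[i] * cd,
                background = cat$sensitivity[i],
                cat$sensitivity[i] * (1 + config$matrix_trend * cd))
    if (h == 0) next
    win <- which(abs(axis - cat$center[i]) <= 8 * cat$width[i])
    if (!length(win)) win <- which.min(abs(axis - cat$center[i]))
    out[win] <- out[win] +
      line_profile(cat$center[i], cat$width[i], h, axis[win], config$eta)
  }
  out
}

baseline_on_axis <- function(config) {
  axis <- build_axis(config$axis_min, config$axis_max, config$n_channels)
  u <- (axis - config$axis_min) / (config$axis_max - config$axis_min)
  drop(outer(u, seq_along(config$baseline) - 1, `^`) %*% config$baseline)
}

#' Simulate a single LIBS spectrum
#'
#' One recorded spectrum is the average of `config$replicates` shots sharing
#' the sample's Cd content but not the shot factor: each shot is
#' `baseline + f * (sum of line profiles) + additive noise`, with `f` one
#' lognormal draw common to all lines of the shot. Uses the current RNG state;
#' call `set.seed()` for reproducibility.
#'
#' @param config a [simulation_config()].
#' @param cd Cd concentration (mg g^-1), >= 0.
#' @param id sample identifier.
#' @return A list of class `libs_spectrum` with `wavelengths`, `intensities`,
#'   `id`, `cd`.
#' @export
simulate_sample <- function(config, cd, id = "s1") {
  stopifnot(inherits(config, "libs_sim_config"))
  if (!is.finite(cd) || cd < 0) stop("cd must be finite and >= 0")
  axis <- build_axis(config$axis_min, config$axis_max, config$n_channels)
  signal <- line_sum(config, cd)
  base <- baseline_on_axis(config)
  acc <- numeric(length(axis))
  for (r in seq_len(config$replicates)) {
    f <- if (config$shot_sigma > 0)
      rlnorm(1, meanlog = -config$shot_sigma^2 / 2, sdlog = config$shot_sigma)
    else 1
    shot <- base + f * signal
    if (config$noise_sd > 0)
      shot <- shot + rnorm(length(axis), sd = config$noise_sd)
    acc <- acc + shot
  }
  structure(list(wavelengths = axis, intensities = acc / config$replicates,
                 id = id, cd = cd),
            class = "libs_spectrum")
}

#' @export
print.libs_spectrum <- function(x, ...) {
  cat("<libs_spectrum> ", x$id, ": ", length(x$wavelengths), " channels, Cd ",
      format(x$cd, digits = 4), " mg/g\n", sep = "")
  invisible(x)
}

# truncated-at-zero normal draws (rejection sampling); mean/sd recycle
rnorm_trunc0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean                       # sd == 0 entries stay at their mean
  todo <- which(sd > 0)
  while (length(todo)) {
    draw <- rnorm(length(todo), mean[todo], sd[todo])
    ok <- draw >= 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Simulate a complete LIBS dataset
#'
#' Draws each sample's Cd content from its group's truncated normal
#' distribution, simulates the replicate-averaged spectrum with
#' [simulate_sample()], and returns a [spectral_dataset()] carrying the true
#' concentrations as reference values. Fully reproducible given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A `libs_dataset`.
#' @examples
#' cfg <- simulation_config(n_per_group = rep(2, 5), n_channels = 200,
#'                          replicates = 2, seed = 1)
#' simulate_dataset(cfg)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "libs_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sum(config$n_per_group)
  group <- rep(seq_along(config$n_per_group), config$n_per_group)
  cd <- rnorm_trunc0(n, config$group_means[group], config$group_sds[group])
  ids <- sprintf("g%d_s%02d", group, sequence(config$n_per_group))
  mat <- matrix(0, n, config$n_channels)
  for (i in seq_len(n))
    mat[i, ] <- simulate_sample(config, cd[i], ids[i])$intensities
  axis <- build_axis(config$axis_min, config$axis_max, config$n_channels)
  spectral_dataset(axis, mat, cd, ids)
}
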