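test_that("build_axis produces uniform grids with exact endpoints", {
  a <- build_axis(229.99, 880.01, 22015)
  expect_length(a, 22015)
  expect_identical(a[1], 229.99)
  expect_identical(a[22015], 880.01)
  sp <- diff(a)
  expect_equal(sp[1], (880.01 - 229.99) / 22014, tolerance = 1e-12)
  expect_lt(max(sp) - min(sp), 1e-9)

  expect_equal(build_axis(0, 1, 2), c(0, 1))
  expect_equal(diff(build_axis(0, 10, 11)), rep(1, 10))
  expect_error(build_axis(5, 1, 10), "exceed")
  expect_error(build_axis(0, 1, 1), ">= 2")
})

test_that("line_profile peaks at the channel nearest center and halves at FWHM/2", {
  axis <- seq(500, 520, by = 0.05)
  expect_equal(line_profile(508.58, 0.1, 0, axis), numeric(length(axis)))

  prof <- line_profile(510, 0.1, 7, axis)           # center on-grid
  expect_equal(max(prof), 7)
  expect_equal(prof[which(axis == 510)], 7)

  # Gaussian mix: half maximum at center +- FWHM/2
  fwhm <- 0.4
  axis2 <- seq(509, 511, by = 0.1)                  # contains 510 +- 0.2
  g <- line_profile(510, fwhm, 2, axis2, eta = 0)
  expect_equal(g[which(axis2 == 510 - fwhm / 2)], 1, tolerance = 1e-9)
  expect_equal(g[which(axis2 == 510 + fwhm / 2)], 1, tolerance = 1e-9)

  # off-grid center still carries exactly the requested height
  prof2 <- line_profile(510.013, 0.1, 3, axis)
  expect_equal(max(prof2), 3)
  expect_error(line_profile(510, -1, 1, axis), "width")
})

test_that("simulated peak heights are affine in Cd and reproducible", {
  cfg <- noiseless_config(1, n_channels = 1301)
  s0 <- simulate_sample(cfg, 0)
  s1 <- simulate_sample(cfg, 3)
  s2 <- simulate_sample(cfg, 6)
  h <- function(sp) line_intensity(sp, line_nm = 508.58)
  expect_equal(h(s0), 0)                       # zero concentration, no baseline
  expect_equal(h(s2), 2 * h(s1), tolerance = 1e-12)

  set.seed(42)
  a <- simulate_sample(smoke_config(1), 2.5)
  set.seed(42)
  b <- simulate_sample(smoke_config(1), 2.5)
  expect_identical(a$intensities, b$intensities)
  expect_error(simulate_sample(cfg, -1), "cd")
})

test_that("simulate_dataset respects the group design and seed", {
  cfg <- simulation_config(n_per_group = rep(2, 5), n_channels = 120,
                           replicates = 1, seed = 7)
  d <- simulate_dataset(cfg)
  expect_s3_class(d, "libs_dataset")
  expect_equal(dim(d$intensities), c(10, 120))
  expect_length(d$reference, 10)
  expect_identical(simulate_dataset(cfg)$intensities, d$intensities)
})

test_that("replicate averaging shrinks channel-wise variance", {
  base <- function(reps, seed) simulation_config(
    n_per_group = 1, group_means = 5, group_sds = 0, n_channels = 60,
    replicates = reps, shot_sigma = 0.2, noise_sd = 2, seed = seed)
  ch <- 25
  v <- function(reps) {
    vals <- vapply(1:100, function(s)
      simulate_dataset(base(reps, s))$intensities[1, ch], numeric(1))
    var(vals)
  }
  expect_lt(v(40), v(1) / 5)
})

test_that("drawn concentrations recover the configured group means", {
  # groups with mean >> sd so zero-truncation is negligible
  cfg <- simulation_config(n_per_group = rep(60, 3),
                           group_means = c(2.304, 6.663, 11.577),
                           group_sds = c(0.602, 1.735, 2.617),
                           n_channels = 40, replicates = 1,
                           shot_sigma = 0, noise_sd = 0, seed = 5)
  d <- simulate_dataset(cfg)
  grp <- rep(1:3, each = 60)
  for (g in 1:3) {
    se <- cfg$group_sds[g] / sqrt(60)
    expect_lt(abs(mean(d$reference[grp == g]) - cfg$group_means[g]), 3 * se)
  }
})

test_that("line catalog and dataset round-trip through their text formats", {
  cat0 <- default_line_catalog()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_line_catalog(cat0, f)
  cat1 <- read_line_catalog(f)
  expect_equal(as.data.frame(cat1), as.data.frame(cat0), tolerance = 1e-12)

  d0 <- simulate_dataset(simulation_config(n_per_group = rep(2, 2),
                                           group_means = c(1, 5),
                                           group_sds = c(0.1, 0.5),
                                           n_channels = 50, replicates = 1,
                                           seed = 3))
  fd <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(d0, fd)
  d1 <- read_dataset(fd)
  expect_equal(d1$wavelengths, d0$wavelengths, tolerance = 1e-10)
  expect_equal(d1$intensities, d0$intensities, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(d1$reference, d0$reference, tolerance = 1e-12)
  expect_identical(d1$ids, d0$ids)
})

test_that("simulation config round-trips through YAML + catalog files", {
  cfg <- simulation_config(n_per_group = c(3, 4), group_means = c(1, 6),
                           group_sds = c(0.2, 1), n_channels = 300,
                           replicates = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$n_per_group, cfg$n_per_group)
  expect_equal(cfg2$group_means, cfg$group_means)
  expect_equal(as.data.frame(cfg2$catalog), as.data.frame(cfg$catalog),
               tolerance = 1e-12)
  expect_identical(simulate_dataset(cfg2)$intensities,
                   simulate_dataset(cfg)$intensities)
})

test_that("config validation rejects degenerate designs", {
  expect_error(simulation_config(n_per_group = integer(0)), "group")
  expect_error(simulation_config(group_means = c(1, 2)), "length")
  expect_error(simulation_config(shot_sigma = -0.1), ">= 0")
  expect_error(simulation_config(n_channels = 1), ">= 2")
})
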