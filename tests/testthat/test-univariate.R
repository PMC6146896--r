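test_that("line_intensity reads nearest-channel and window-max values", {
  wl <- seq(500, 510, by = 0.5)
  x <- numeric(length(wl))
  x[wl == 505] <- 9
  expect_equal(line_intensity(wl, x, 505), 9)                 # on-grid
  expect_equal(line_intensity(wl, x, 505.1), 9)               # nearest
  # delta peak one channel off: nearest misses, window_max recovers
  x2 <- numeric(length(wl)); x2[wl == 505.5] <- 7
  expect_equal(line_intensity(wl, x2, 505), 0)
  expect_equal(line_intensity(wl, x2, 505, mode = "window_max", window = 0.5), 7)
  # window max dominates nearest everywhere
  set.seed(1)
  x3 <- runif(length(wl))
  for (nm in c(501, 504.3, 509)) {
    expect_gte(line_intensity(wl, x3, nm, "window_max", 1),
               line_intensity(wl, x3, nm))
  }
  expect_error(line_intensity(wl, x, 499), "outside")
})

test_that("extract_line agrees with per-sample line_intensity", {
  d <- simulate_dataset(smoke_config(3, n_channels = 201))
  v <- extract_line(d, 508.58)
  manual <- vapply(seq_along(d$ids), function(i)
    line_intensity(d$wavelengths, d$intensities[i, ], 508.58), numeric(1))
  expect_equal(v, manual, ignore_attr = TRUE)
})

test_that("ratio indices follow their definitions and are scale-invariant", {
  expect_equal(index1(2, 4, 2), 1.5)
  expect_equal(index1(0, 0, 5), 0)
  expect_equal(index2(3, 1.5), 2)
  expect_equal(index2(0, 7), 0)
  for (c_ in c(0.1, 3, 250)) {
    expect_equal(index1(2 * c_, 4 * c_, 2 * c_), 1.5, tolerance = 1e-12)
    expect_equal(index2(3 * c_, 1.5 * c_), 2, tolerance = 1e-12)
  }
  expect_error(index1(1, 1, 0), "denominator")
  expect_error(index2(1, -2), "denominator")
})

test_that("index values are invariant to the shared shot factor", {
  # two datasets identical except for the shot factor realizations
  mk <- function(shot) simulate_dataset(index_config(5, shot_sigma = shot))
  d <- mk(0.4)
  d0 <- mk(0)
  i2 <- index2(extract_line(d, 508.58), extract_line(d, 466.23))
  i2_0 <- index2(extract_line(d0, 508.58), extract_line(d0, 466.23))
  expect_equal(i2, i2_0, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("univariate calibration is exact on exact affine relations", {
  set.seed(2)
  x <- runif(20, 0, 10)
  y <- 0.8 * x + 1
  s <- split_rank_ordered(y)
  fit <- fit_univariate(x, y, s)
  m <- fit$metrics
  expect_equal(m$r2_cal, 1, tolerance = 1e-10)
  expect_equal(m$r2_pred, 1, tolerance = 1e-10)
  expect_lt(m$rmsecv, 1e-8)
  expect_lt(m$rmsep, 1e-8)
  expect_equal(fit$slope, 0.8, tolerance = 1e-10)
})

test_that("an uncorrelated predictor has no prediction skill", {
  r2p <- vapply(1:20, function(s) {
    set.seed(300 + s)
    y <- runif(24, 0, 10)
    x <- rnorm(24)                        # independent of y
    fit_univariate(x, y, split_rank_ordered(y))$metrics$r2_pred
  }, numeric(1))
  expect_lt(median(r2p), 0.2)
  expect_gt(mean(r2p < 0.5), 0.8)
})

test_that("univariate LOO RMSECV equals the explicit refit oracle", {
  set.seed(4)
  x <- runif(15, 0, 5)
  y <- 2 * x + rnorm(15, sd = 0.4) + 1
  y <- y - min(y)
  s <- split_rank_ordered(y)
  fit <- fit_univariate(x, y, s)
  xc <- x[s$calibration]; yc <- y[s$calibration]
  oracle <- sqrt(mean(vapply(seq_along(xc), function(i) {
    cf <- coef(lm(yc[-i] ~ xc[-i]))
    (yc[i] - (cf[1] + cf[2] * xc[i]))^2
  }, numeric(1))))
  expect_equal(fit$rmsecv, oracle, tolerance = 1e-10)
})

test_that("index2 beats the bare 508.58 nm line under shot noise", {
  wins <- vapply(1:10, function(s) {
    d <- simulate_dataset(index_config(400 + s, shot_sigma = 0.2))
    sp <- split_rank_ordered(d$reference)
    i508 <- extract_line(d, 508.58)
    i466 <- extract_line(d, 466.23)
    r_index <- fit_univariate(index2(i508, i466), d$reference, sp)$metrics$rmsep
    r_line <- fit_univariate(i508, d$reference, sp)$metrics$rmsep
    r_index < r_line
  }, logical(1))
  expect_gte(sum(wins), 8)
})

test_that("lines_in_ranges uses closed intervals over any range set", {
  catalog <- default_line_catalog()
  cd <- catalog[catalog$element == "Cd", ]
  expect_equal(nrow(lines_in_ranges(cd, data.frame(a = numeric(0),
                                                   b = numeric(0)))), 0)
  ranges <- data.frame(min = c(323, 451, 523, 631, 474),
                       max = c(390, 521, 546, 662, 526))
  expect_equal(sort(lines_in_ranges(cd, ranges)$center),
               sort(cd$center))          # all ten Cd I lines
  # endpoint inclusion
  expect_equal(nrow(lines_in_ranges(cd, data.frame(508.58, 508.58))), 1)
})

test_that("univariate_table reports one row of metrics per line", {
  d <- simulate_dataset(index_config(9, shot_sigma = 0.1, noise_sd = 1))
  sp <- split_rank_ordered(d$reference)
  tab <- univariate_table(d, sp)
  expect_equal(nrow(tab), 10)            # the ten Cd I lines
  expect_true(all(tab$rmsecv >= 0) && all(tab$rmsep >= 0))
  expect_true(all(tab$r2_cal <= 1))
  # the strong clean line should be among the best predictors
  expect_gte(tab$r2_pred[tab$line_nm == 508.58], max(tab$r2_pred) - 0.05)
})
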