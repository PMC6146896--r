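test_that("equidistant partition follows the remainder-first convention", {
  p28 <- partition_equidistant(22015, 28)
  sz <- interval_sizes(p28)
  expect_equal(sz[1:7], rep(787L, 7))
  expect_equal(sz[8:28], rep(786L, 21))

  expect_equal(interval_sizes(partition_equidistant(22015, 13))[8], 1693L)
  expect_equal(interval_sizes(partition_equidistant(10, 3)), c(4L, 3L, 3L))

  # coverage, disjointness and the size-gap bound across many (p, k)
  set.seed(2)
  for (i in 1:25) {
    p <- sample(10:500, 1)
    k <- sample(seq_len(p), 1)
    part <- partition_equidistant(p, k)
    sz <- interval_sizes(part)
    expect_equal(sum(sz), p)
    expect_lte(max(sz) - min(sz), 1L)
    expect_true(all(diff(sz) <= 0))       # larger intervals first
    expect_identical(interval_channels(part, seq_len(k)), seq_len(p))
  }
  expect_error(partition_equidistant(10, 11), "exceed")
  expect_error(partition_equidistant(10, 0), ">= 1")
})

test_that("replaying a removal order reproduces the channel bookkeeping", {
  part <- partition_equidistant(10, 3)        # sizes 4, 3, 3
  expect_equal(replay_elimination(part, c(2, 3, 1)), c(10L, 7L, 4L))
  expect_equal(replay_elimination(part, c(1, 2, 3)), c(10L, 6L, 3L))
  expect_error(replay_elimination(part, c(1, 1, 2)), "permutation")
})

test_that("interval_score is exact in the noiseless limit and symmetric", {
  set.seed(3)
  n <- 10
  x <- rnorm(n)
  # one informative channel among inert (constant) ones: exact at 1 LV
  X <- cbind(x, matrix(2, n, 3))
  y <- 2 * x + 1
  d <- spectral_dataset(1:4, X, y - min(y))
  sc <- interval_score(d, 1:4, max_lv = 3)
  expect_lt(sc$rmsecv, 1e-6)
  expect_identical(sc$n_lv, 1L)

  # full-rank noiseless design: exact once all latent variables are allowed
  X2 <- cbind(x, matrix(rnorm(n * 3), n))
  d2 <- spectral_dataset(1:4, X2, y - min(y))
  sc_full <- interval_score(d2, 1:4, max_lv = 4)
  expect_lt(sc_full$rmsecv, 1e-6)

  # invariance to channel ordering within the set
  sc2 <- interval_score(d2, c(3, 1, 4, 2), max_lv = 4)
  expect_equal(sc2$rmsecv, sc_full$rmsecv, tolerance = 1e-12)
})

test_that("constant channels score as the leave-one-out mean predictor", {
  y <- c(1, 3, 4, 8, 9)
  d <- spectral_dataset(1:3, matrix(5, 5, 3), y)
  sc <- interval_score(d, 1:3, max_lv = 2)
  oracle <- sqrt(mean(vapply(1:5, function(i) (y[i] - mean(y[-i]))^2,
                             numeric(1))))
  expect_equal(sc$rmsecv, oracle, tolerance = 1e-10)
  expect_identical(sc$n_lv, 0L)
})

test_that("iPLS finds the informative interval and is scale-invariant", {
  d <- simulate_dataset(selection_config(7, shot_sigma = 0, noise_sd = 1))
  ch508 <- which.min(abs(d$wavelengths - 508.58))
  sel <- ipls_select(d, k_range = 2:12, max_lv = 4)
  expect_true(ch508 %in% sel$channels)
  expect_true(all(sel$ledger$rmsecv >= sel$rmsecv))

  d10 <- spectral_dataset(d$wavelengths, d$intensities * 10,
                          d$reference, d$ids)
  sel10 <- ipls_select(d10, k_range = 2:12, max_lv = 4)
  expect_identical(sel10$channels, sel$channels)
})

test_that("iPLS with a single candidate interval returns the full spectrum", {
  d <- simulate_dataset(smoke_config(5, n_channels = 60))
  sel <- ipls_select(d, k_range = 1, max_lv = 3)
  expect_identical(sel$channels, seq_along(d$wavelengths))
})

test_that("BiPLS ledger conserves channel counts and ends at one interval", {
  d <- simulate_dataset(selection_config(13, shot_sigma = 0, noise_sd = 1))
  el <- bipls_eliminate(d, k = 6, max_lv = 4)
  led <- el$ledger
  expect_equal(nrow(led), 6)
  expect_equal(led$n_intervals, 6:1)
  sizes <- interval_sizes(el$partition)
  expect_equal(led$n_channels,
               replay_elimination(el$partition, led$removed))
  expect_true(all(diff(led$n_channels) < 0))
  # the informative interval must survive to the end
  ch508 <- which.min(abs(d$wavelengths - 508.58))
  expect_true(ch508 %in% interval_channels(el$partition, led$removed[6]))
})

test_that("BiPLS with k = 2 performs one comparison and keeps the better half", {
  d <- simulate_dataset(selection_config(17, shot_sigma = 0, noise_sd = 1))
  el <- bipls_eliminate(d, k = 2, max_lv = 4)
  led <- el$ledger
  expect_equal(nrow(led), 2)
  part <- el$partition
  s1 <- interval_score(d, interval_channels(part, 1), 4)$rmsecv
  s2 <- interval_score(d, interval_channels(part, 2), 4)$rmsecv
  expect_identical(led$removed[1], which.max(c(s1, s2)))
})

test_that("bipls_select shrinks to the informative interval set", {
  d <- simulate_dataset(selection_config(19, shot_sigma = 0, noise_sd = 1))
  sel <- bipls_select(d, k_range = c(6, 10), max_lv = 4)
  ch508 <- which.min(abs(d$wavelengths - 508.58))
  expect_true(ch508 %in% sel$channels)
  # channel count equals the sum of selected interval sizes
  part <- partition_equidistant(length(d$wavelengths), sel$k)
  expect_equal(length(sel$channels),
               sum(interval_sizes(part)[sel$intervals]))
  # wavelength ranges map back onto the selected indices
  rr <- sel$wavelength_ranges
  covered <- unlist(lapply(seq_len(nrow(rr)), function(i)
    which(d$wavelengths >= rr$min_nm[i] & d$wavelengths <= rr$max_nm[i])))
  expect_setequal(covered, sel$channels)
})
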