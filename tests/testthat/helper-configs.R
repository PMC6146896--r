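# Shared fixture builders. All datasets are generated in code at test time.

# catalog in which Cd I 508.58 nm is the only concentration-sensitive line;
# matrix lines (no Cd trend) and the background-like 466.23 nm line remain,
# so the only ground-truth informative channels are those under 508.58 nm
single_line_catalog <- function() {
  cat <- default_line_catalog()
  cat$sensitivity[cat$kind == "analyte" & cat$center != 508.58] <- 0
  cat
}

# reduced-axis config used by the selection-correctness suites. Pure Gaussian
# profiles (eta = 0) on a 1 nm grid confine each 0.1 nm-wide line to the
# single channel nearest its center, so "the interval containing the channel
# nearest 508.58 nm" is the unambiguous ground truth; Lorentzian wings would
# smear genuine analyte signal into neighbouring intervals and make the
# oracle ill-posed at this grid spacing.
selection_config <- function(seed, shot_sigma = 0.2, noise_sd = 1) {
  simulation_config(n_per_group = rep(5, 5), n_channels = 651,
                    replicates = 3, catalog = single_line_catalog(),
                    shot_sigma = shot_sigma, noise_sd = noise_sd,
                    matrix_trend = 0, eta = 0, seed = seed)
}

# fully deterministic config: no shot factor, no additive noise, no
# matrix-line drift -- intensities are exact affine functions of Cd content
noiseless_config <- function(seed, n_channels = 1301, n_per_group = rep(4, 5)) {
  simulation_config(n_per_group = n_per_group, n_channels = n_channels,
                    replicates = 1, shot_sigma = 0, noise_sd = 0,
                    matrix_trend = 0, seed = seed)
}

# small all-purpose noisy config for pipeline smoke tests
smoke_config <- function(seed, n_channels = 401) {
  simulation_config(n_per_group = rep(8, 5), n_channels = n_channels,
                    replicates = 2, shot_sigma = 0.1, noise_sd = 1,
                    seed = seed)
}

# index-mechanism config: fine enough that 466.23 and 467.81 nm fall on
# distinct channels; additive noise off by default (the mechanism under test
# is multiplicative)
index_config <- function(seed, shot_sigma = 0.2, noise_sd = 0) {
  simulation_config(n_per_group = rep(5, 5), n_channels = 1301,
                    replicates = 3, shot_sigma = shot_sigma,
                    noise_sd = noise_sd, seed = seed)
}

# brute-force SPA oracle: classical Gram-Schmidt via least-squares residuals
spa_oracle_chain <- function(X, start, p_max) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  nrm <- sqrt(colSums(Xc^2))
  Z <- sweep(Xc, 2, ifelse(nrm > 0, nrm, 1), "/")
  selected <- start
  while (length(selected) < p_max) {
    rest <- setdiff(seq_len(ncol(Z)), selected)
    if (!length(rest)) break
    resnorm <- vapply(rest, function(j) {
      fit <- lm.fit(Z[, selected, drop = FALSE], Z[, j])
      sqrt(sum(fit$residuals^2))
    }, numeric(1))
    if (max(resnorm) <= 1e-10) break
    selected <- c(selected, rest[which.max(resnorm)])
  }
  selected
}
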