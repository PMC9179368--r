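# Shared fixtures: deterministic, noise-free configurations used across
# the module tests.

# a config with every nuisance switched off (pure class signal)
clean_config <- function(params = regime_params("3T-original"),
                         basis = default_basis()) {
  basis$amplitude_cv <- 0
  sim_config(
    basis = basis, params = params,
    noise_sd = 0, baseline_amplitude = 0, ppm_jitter_sd = 0,
    global_scale_range = c(1, 1)
  )
}

# single-peak basis (unit choline at 3.22 ppm unless overridden)
single_peak_basis <- function(position = 3.22, amplitude = 1,
                              fwhm_hz = 10) {
  tibble::tibble(
    name = "peak", position_ppm = position, fwhm_hz = fwhm_hz,
    amplitude = amplitude, amplitude_cv = 0, mult_mut = 1, mult_wt = 1
  )
}

# acquisition params whose ppm axis coincides exactly with a reference
# grid's window axis (for feeding harmonized output back in as raw data)
regrid_params <- function(grid) {
  g <- grid$ppm
  n <- length(g)
  step <- g[1] - g[2]
  f0 <- grid$params$transmitter_frequency
  acq_params(grid$params$field_strength, n * step * f0, n,
             transmitter_frequency = f0, center_ppm = g[1] - n * step / 2)
}

# constructed classification data: p noise columns, two informative
# columns shifted in opposite directions for the mut class
two_feature_data <- function(seed, n_per = 50, p = 50, shift = 3) {
  set.seed(seed)
  cols <- if (p >= 23) c(7, 23) else c(2, p)
  y <- rep(c("mut", "wt"), each = n_per)
  X <- matrix(stats::rnorm(2 * n_per * p), 2 * n_per, p)
  X[y == "mut", cols[1]] <- X[y == "mut", cols[1]] + shift
  X[y == "mut", cols[2]] <- X[y == "mut", cols[2]] - shift
  list(X = X, y = y, cols = cols)
}
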