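test_that("choline detection finds the peak, with and without jitter", {
  cfg <- clean_config()
  sp <- simulate_spectrum(cfg, "wt", seed = 1)
  step <- ppm_axis(cohort_params(sp)[[1]])[1] -
    ppm_axis(cohort_params(sp)[[1]])[2]
  expect_lt(abs(detect_choline(sp) - 3.22), step)

  shifted <- cfg
  shifted$basis$position_ppm <- shifted$basis$position_ppm + 0.05
  sps <- simulate_spectrum(shifted, "wt", seed = 1)
  expect_lt(abs(detect_choline(sps) - 3.27), step)
})

test_that("flat spectra resolve ties to the grid point nearest 3.22 ppm", {
  p <- acq_params(3, 1200, 1024)
  flat <- mrs_cohort("z", list(numeric(1024)), p)
  ax <- ppm_axis(p)
  expect_equal(detect_choline(flat), ax[which.min(abs(ax - 3.22))])
})

test_that("a spectrum already on the reference grid harmonizes to itself", {
  grid <- reference_grid()
  ax <- ppm_axis(grid$params)
  # put choline exactly on a grid node so the alignment shift is zero
  cho_node <- ax[which.min(abs(ax - 3.22))]
  b <- default_basis()
  b$amplitude_cv <- 0
  b$position_ppm <- b$position_ppm + (cho_node - 3.22)
  cfg <- sim_config(basis = b, noise_sd = 0, baseline_amplitude = 0,
                    ppm_jitter_sd = 0, global_scale_range = c(1, 1))
  sp <- simulate_spectrum(cfg, "mut", seed = 1)
  grid2 <- reference_grid(anchor_ppm = cho_node)
  h <- harmonize_cohort(sp, grid2, normalize = FALSE)
  expect_equal(h$applied_shift, 0, tolerance = 1e-12)
  keep <- ax <= grid2$window[1] & ax >= grid2$window[2]
  expect_equal(h$intensities[[1]], sp$intensities[[1]][keep],
               tolerance = 1e-12)
})

test_that("an injected global shift is undone by alignment", {
  cfg <- clean_config()
  delta <- 0.04
  shifted <- cfg
  shifted$basis$position_ppm <- shifted$basis$position_ppm + delta
  sp <- simulate_spectrum(shifted, "wt", seed = 2)
  h <- harmonize_cohort(sp)
  step <- ppm_step(cohort_params(sp)[[1]])
  expect_lt(abs(h$applied_shift - (-delta)), step)
})

test_that("normalization fixes the window integral at one and records the factor", {
  co <- simulate_cohort(sim_config(), 2, 2, seed = 8)
  h <- harmonize_cohort(co)
  grid <- attr(h, "grid")
  for (i in seq_len(nrow(h))) {
    y <- h$intensities[[i]]
    area <- sum((y[-1] + y[-length(y)]) / 2 * abs(diff(grid$ppm)))
    expect_equal(area, 1, tolerance = 1e-9)
    expect_gt(h$normalization_factor[i], 0)
  }
})

test_that("positive rescaling of the raw spectrum leaves the result unchanged", {
  co <- simulate_cohort(sim_config(), 1, 1, seed = 13)
  h1 <- harmonize_cohort(co)
  scaled <- co
  scaled$intensities <- lapply(co$intensities, function(y) y * 7)
  h7 <- harmonize_cohort(scaled)
  for (i in seq_len(nrow(h1))) {
    expect_equal(h7$intensities[[i]], h1$intensities[[i]],
                 tolerance = 1e-9)
  }
})

test_that("harmonizing twice equals harmonizing once on noiseless spectra", {
  b <- default_basis()
  b$amplitude_cv <- 0
  b$position_ppm <- b$position_ppm + 0.03  # global calibration error
  cfg <- sim_config(basis = b, noise_sd = 0, baseline_amplitude = 0,
                    ppm_jitter_sd = 0, global_scale_range = c(1, 1))
  co <- dplyr::bind_rows(
    simulate_spectrum(cfg, "mut", seed = 1, id = "m"),
    simulate_spectrum(cfg, "wt", seed = 2, id = "w")
  )
  grid <- reference_grid()
  h1 <- harmonize_cohort(mrs_cohort(co$id, co$intensities,
                                    cohort_params(co), co$label), grid)
  # feed the harmonized output back in as a raw cohort on the grid axis
  co2 <- mrs_cohort(h1$id, h1$intensities, regrid_params(grid), h1$label)
  h2 <- harmonize_cohort(co2, grid)
  expect_equal(h2$applied_shift, c(0, 0))
  for (i in 1:2) {
    expect_equal(h2$intensities[[i]], h1$intensities[[i]],
                 tolerance = 1e-9)
    expect_equal(h2$normalization_factor[i], 1, tolerance = 1e-9)
  }
})

test_that("the same signal acquired at 1.5 T and 3 T harmonizes consistently", {
  b <- default_basis()
  b$amplitude_cv <- 0
  s3 <- simulate_spectrum(clean_config(regime_params("3T-original"), b),
                          "mut", seed = 1)
  s15 <- simulate_spectrum(clean_config(regime_params("1.5T-validation"), b),
                           "mut", seed = 1)
  h3 <- harmonize_cohort(s3, normalize = FALSE)
  h15 <- harmonize_cohort(s15, normalize = FALSE)
  v3 <- h3$intensities[[1]]
  v15 <- h15$intensities[[1]]
  cho_height <- max(v3)
  expect_lt(max(abs(v3 - v15)), 0.05 * cho_height)
  expect_gt(stats::cor(v3, v15), 0.99)

  n3 <- harmonize_cohort(s3)$intensities[[1]]
  n15 <- harmonize_cohort(s15)$intensities[[1]]
  expect_gt(stats::cor(n3, n15), 0.99)
})

test_that("degenerate and uncoverable spectra raise informative errors", {
  p <- acq_params(3, 1200, 1024)
  flat <- mrs_cohort("z", list(numeric(1024)), p)
  expect_error(harmonize_cohort(flat), "non-positive integral")

  # axis covers the choline search window but not the analysis window
  narrow <- acq_params(3, 200, 256, center_ppm = 3.5)
  co <- mrs_cohort("n", list(stats::rnorm(256)), narrow)
  expect_error(harmonize_cohort(co), "cover the analysis window")

  # and an axis missing the choline search window errors in detection
  off <- acq_params(3, 200, 256, center_ppm = 1.0)
  co2 <- mrs_cohort("o", list(stats::rnorm(256)), off)
  expect_error(harmonize_cohort(co2), "choline search window")
})
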