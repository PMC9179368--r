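#' Default metabolite basis for spectrum simulation
#'
#' One row per resonance: name, chemical-shift position (ppm), full width
#' at half maximum (Hz, quoted at 3.0 T and scaled proportionally with
#' field strength, i.e. constant in ppm), mean amplitude (arbitrary
#' units, unit Lorentzian peak height), per-spectrum amplitude coefficient
#' of variation, and group multipliers for the IDH-mutant and wild-type
#' classes.
#'
#' The group structure encodes the mutation-specific spectral signature:
#' 2-hydroxyglutarate at 2.24 ppm is present only in mutant spectra,
#' myo-inositol at 3.53 ppm is elevated in mutants, and the lactate/lipid
#' methylene signal near 1.3 ppm is elevated in wild-type spectra; choline,
#' creatine, NAA and Glx are class-neutral. Amplitudes are scaled so that
#' the quality-gate thresholds (choline > 0.2, creatine > 0.1) are
#' meaningful on a unit-scale spectrum.
#'
#' @return A tibble with columns `name`, `position_ppm`, `fwhm_hz`,
#'   `amplitude`, `amplitude_cv`, `mult_mut`, `mult_wt`.
#' @examples
#' default_basis()
#' @export
default_basis <- function() {
  tibble::tribble(
    ~name,      ~position_ppm, ~fwhm_hz, ~amplitude, ~amplitude_cv, ~mult_mut, ~mult_wt,
    "NAA",       2.01,         10,        1.2,        0.25,          1,         1,
    "Cr",        3.03,         10,        0.8,        0.25,          1,         1,
    "Cr2",       3.93,         10,        0.3,        0.25,          1,         1,
    "Cho",       3.22,         10,        1.0,        0.25,          1,         1,
    "M-Ins",     3.53,         10,        0.4,        0.25,          1.75,      1,
    "Glx",       2.35,         10,        0.5,        0.25,          1,         1,
    "2-HG",      2.24,         10,        0.25,       0.25,          1,         0,
    "Lac/Lip",   1.30,         10,        0.5,        0.25,          0.4,       1
  )
}

#' Simulation configuration
#'
#' Collects everything [simulate_spectrum()] needs: the metabolite basis,
#' the acquisition regime, and the nuisance model (noise, smooth baseline,
#' a global ppm calibration jitter, and a per-spectrum arbitrary-unit
#' scale).
#'
#' @param basis Metabolite basis tibble, see [default_basis()].
#' @param params Acquisition parameters, see [acq_params()].
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to
#'   every point (arbitrary units).
#' @param baseline_amplitude Maximum absolute value of the random smooth
#'   baseline (arbitrary units); 0 disables it.
#' @param baseline_order Polynomial order of the baseline (small integer).
#' @param ppm_jitter_sd Standard deviation of the per-spectrum global
#'   frequency-calibration shift, in ppm.
#' @param global_scale_range Two positive numbers `(low, high)`; each
#'   spectrum is multiplied by a scale drawn uniformly from this range,
#'   emulating vendor arbitrary units.
#' @param fwhm_reference_tesla Field strength at which `fwhm_hz` in the
#'   basis is quoted; linewidths in Hz scale proportionally with field so
#'   the width in ppm is field-invariant.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(basis = default_basis(),
                       params = regime_params("3T-original"),
                       noise_sd = 0.05,
                       baseline_amplitude = 0.1,
                       baseline_order = 3,
                       ppm_jitter_sd = 0.01,
                       global_scale_range = c(0.5, 2),
                       fwhm_reference_tesla = 3.0) {
  stopifnot(
    inherits(params, "acq_params"),
    is.data.frame(basis),
    all(c("name", "position_ppm", "fwhm_hz", "amplitude",
          "amplitude_cv", "mult_mut", "mult_wt") %in% names(basis)),
    all(basis$fwhm_hz > 0), all(basis$amplitude >= 0),
    all(basis$amplitude_cv >= 0),
    all(basis$mult_mut >= 0), all(basis$mult_wt >= 0),
    noise_sd >= 0, baseline_amplitude >= 0, baseline_order >= 0,
    ppm_jitter_sd >= 0,
    length(global_scale_range) == 2,
    all(global_scale_range > 0),
    global_scale_range[1] <= global_scale_range[2]
  )
  structure(
    list(
      basis = tibble::as_tibble(basis), params = params,
      noise_sd = noise_sd, baseline_amplitude = baseline_amplitude,
      baseline_order = as.integer(baseline_order),
      ppm_jitter_sd = ppm_jitter_sd,
      global_scale_range = as.numeric(global_scale_range),
      fwhm_reference_tesla = fwhm_reference_tesla
    ),
    class = "sim_config"
  )
}

# unit-height absorption-mode Lorentzian
lorentzian <- function(x, center, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((x - center)^2 + hw2)
}

#' Simulate a single spectrum
#'
#' Draws one synthetic spectrum of the given class. The clean signal is a
#' sum of unit-height Lorentzians (one per basis resonance) with
#' log-normal per-peak amplitude variation and the class multiplier
#' applied; a single global ppm jitter shifts all resonances together
#' (frequency-calibration error). A random smooth polynomial baseline and
#' white Gaussian noise are added, and the whole spectrum is multiplied by
#' a random arbitrary-unit scale.
#'
#' @param config A [sim_config()].
#' @param label `"mut"` or `"wt"`.
#' @param seed Integer seed; the same seed reproduces the same spectrum.
#' @param id Spectrum identifier.
#' @return A one-row [mrs_cohort()] tibble.
#' @export
simulate_spectrum <- function(config, label, seed, id = label) {
  stopifnot(inherits(config, "sim_config"))
  label <- normalize_label(label)
  stopifnot(label %in% c("mut", "wt"))
  with_seed_local(seed, {
    ax <- ppm_axis(config$params)
    # linewidth constant in ppm: Hz width quoted at the reference field
    fwhm_ppm <- config$basis$fwhm_hz /
      (gyromagnetic_mhz_per_t * config$fwhm_reference_tesla)
    mult <- if (label == "mut") config$basis$mult_mut else config$basis$mult_wt
    jitter <- if (config$ppm_jitter_sd > 0) {
      stats::rnorm(1, 0, config$ppm_jitter_sd)
    } else 0
    sig <- numeric(length(ax))
    for (j in seq_len(nrow(config$basis))) {
      cv <- config$basis$amplitude_cv[j]
      amp_fac <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        stats::rlnorm(1, meanlog = -sdl^2 / 2, sdlog = sdl)  # mean 1
      } else 1
      amp <- config$basis$amplitude[j] * mult[j] * amp_fac
      if (amp > 0) {
        sig <- sig + amp *
          lorentzian(ax, config$basis$position_ppm[j] + jitter, fwhm_ppm[j])
      }
    }
    scale <- stats::runif(1, config$global_scale_range[1],
                          config$global_scale_range[2])
    base <- if (config$baseline_amplitude > 0) {
      random_baseline(length(ax), config$baseline_order,
                      config$baseline_amplitude)
    } else 0
    noise <- if (config$noise_sd > 0) {
      stats::rnorm(length(ax), 0, config$noise_sd)
    } else 0
    mrs_cohort(id, list(scale * sig + base + noise), config$params,
               label = label)
  })
}

# smooth random polynomial, shifted and rescaled into [0, amplitude];
# short-TE in vivo baselines are broad, smooth and predominantly positive
# (macromolecule / lipid background), and a non-negative baseline keeps
# the window integral of every spectrum positive
random_baseline <- function(n, order, amplitude) {
  x <- seq(-1, 1, length.out = n)
  co <- stats::rnorm(order + 1)
  b <- drop(outer(x, 0:order, `^`) %*% co)
  rng <- max(b) - min(b)
  if (rng == 0) return(rep(amplitude / 2, n))
  (b - min(b)) * amplitude / rng
}

#' Simulate a labeled cohort
#'
#' Generates `n_mut + n_wt` spectra under one configuration. Each spectrum
#' uses a sub-seed derived deterministically from the master seed and the
#' spectrum's position, so a cohort is reproducible and unaffected by
#' generation order.
#'
#' @param config A [sim_config()].
#' @param n_mut,n_wt Number of IDH-mutant and wild-type spectra.
#' @param seed Master integer seed.
#' @param prefix Id prefix.
#' @return An [mrs_cohort()] tibble with `n_mut` rows labeled `"mut"`
#'   followed by `n_wt` labeled `"wt"`.
#' @examples
#' co <- simulate_cohort(sim_config(), n_mut = 2, n_wt = 3, seed = 7)
#' table(co$label)
#' @export
simulate_cohort <- function(config, n_mut, n_wt, seed = 1, prefix = "sim") {
  stopifnot(n_mut >= 0, n_wt >= 0)
  labels <- c(rep("mut", n_mut), rep("wt", n_wt))
  if (!length(labels)) {
    stop("Empty cohort requested (n_mut + n_wt = 0).", call. = FALSE)
  }
  rows <- lapply(seq_along(labels), function(i) {
    simulate_spectrum(
      config, labels[i],
      seed = sub_seed(seed, i),
      id = sprintf("%s_%s_%03d", prefix, labels[i], i)
    )
  })
  out <- as_mrs_cohort(dplyr::bind_rows(rows))
  attr(out, "exclusion_ledger") <- empty_ledger()
  out
}

# counter-derived sub-stream seed, kept inside 32-bit integer range
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i) %% 2147483647)
}

# evaluate expr under a temporary RNG state
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
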