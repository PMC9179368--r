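#' Acquisition parameters of a single-voxel MR spectrum
#'
#' Bundles the scanner settings that determine the chemical-shift (ppm) axis
#' of a spectrum: static field strength, transmitter frequency, spectral
#' width, and the number of acquired data points. The echo time is carried
#' as metadata only.
#'
#' If `transmitter_frequency` is not given it is derived from the proton
#' gyromagnetic ratio as `42.576 * field_strength` MHz (so 1.5 T gives
#' 63.864 MHz and 3.0 T gives 127.728 MHz). Real magnets deviate slightly
#' from the nominal field; pass the true synthesizer frequency for measured
#' data.
#'
#' @param field_strength Static field strength in tesla (> 0).
#' @param spectral_width Acquisition bandwidth in Hz (> 0).
#' @param n_points Number of data points in the spectrum (>= 2).
#' @param transmitter_frequency Proton transmitter frequency in MHz;
#'   defaults to `42.576 * field_strength`.
#' @param echo_time Echo time in ms (metadata only; may be `NA`).
#' @param center_ppm Chemical shift at the center of the acquisition
#'   window, in ppm. Defaults to 4.7 (water).
#'
#' @return An object of class `acq_params`: a named list with the fields
#'   above.
#' @examples
#' acq_params(3.0, 1200, 1024)
#' ppm_axis(acq_params(1.5, 1000, 1024))[1:3]
#' @export
acq_params <- function(field_strength, spectral_width, n_points,
                       transmitter_frequency = NULL,
                       echo_time = NA_real_, center_ppm = 4.7) {
  if (!is.numeric(field_strength) || length(field_strength) != 1 ||
      !is.finite(field_strength) || field_strength <= 0) {
    stop("`field_strength` must be a single positive number (tesla).",
         call. = FALSE)
  }
  if (!is.numeric(spectral_width) || length(spectral_width) != 1 ||
      !is.finite(spectral_width) || spectral_width <= 0) {
    stop("`spectral_width` must be a single positive number (Hz).",
         call. = FALSE)
  }
  n_points <- as.integer(n_points)
  if (length(n_points) != 1 || is.na(n_points) || n_points < 2) {
    stop("`n_points` must be a single integer >= 2.", call. = FALSE)
  }
  if (is.null(transmitter_frequency)) {
    transmitter_frequency <- gyromagnetic_mhz_per_t * field_strength
  }
  if (!is.finite(transmitter_frequency) || transmitter_frequency <= 0) {
    stop("`transmitter_frequency` must be positive (MHz).", call. = FALSE)
  }
  structure(
    list(
      field_strength = as.numeric(field_strength),
      transmitter_frequency = as.numeric(transmitter_frequency),
      spectral_width = as.numeric(spectral_width),
      n_points = n_points,
      echo_time = as.numeric(echo_time),
      center_ppm = as.numeric(center_ppm)
    ),
    class = "acq_params"
  )
}

# nominal proton gyromagnetic ratio, MHz per tesla
gyromagnetic_mhz_per_t <- 42.576

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "<acq_params> %.2f T (%.3f MHz), SW %.0f Hz, %d pts, TE %s ms, center %.2f ppm\n",
    x$field_strength, x$transmitter_frequency, x$spectral_width,
    x$n_points, ifelse(is.na(x$echo_time), "?", format(x$echo_time)),
    x$center_ppm
  ))
  invisible(x)
}

#' Acquisition parameters of the two reference regimes
#'
#' Convenience constructor for the two acquisition set-ups the pipeline is
#' built around: the 3.0 T training regime (1200 Hz spectral width) and the
#' 1.5 T validation regime (1000 Hz), both with 1024 data points and a
#' short echo time of 30 ms.
#'
#' @param regime `"3T-original"` or `"1.5T-validation"`.
#' @return An [acq_params()] object.
#' @examples
#' regime_params("1.5T-validation")
#' @export
regime_params <- function(regime = c("3T-original", "1.5T-validation")) {
  regime <- match.arg(regime)
  switch(regime,
    "3T-original" = acq_params(3.0, 1200, 1024L, echo_time = 30),
    "1.5T-validation" = acq_params(1.5, 1000, 1024L, echo_time = 30)
  )
}

#' Chemical-shift axis of a spectrum
#'
#' Computes the ppm coordinate of every data point. The axis spans
#' `spectral_width / transmitter_frequency` ppm, is uniformly spaced with
#' step `span / n_points`, runs from high to low ppm (NMR plotting
#' convention), and starts at `center_ppm + span / 2`.
#'
#' @param params An [acq_params()] object.
#' @return Numeric vector of length `n_points`, strictly decreasing.
#' @examples
#' ax <- ppm_axis(acq_params(3.0, 1200, 1024))
#' range(ax)
#' @export
ppm_axis <- function(params) {
  stopifnot(inherits(params, "acq_params"))
  span <- params$spectral_width / params$transmitter_frequency
  step <- span / params$n_points
  params$center_ppm + span / 2 - step * (seq_len(params$n_points) - 1)
}

# step size of a params' ppm axis
ppm_step <- function(params) {
  (params$spectral_width / params$transmitter_frequency) / params$n_points
}
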