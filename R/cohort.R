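#' Build a spectrum cohort tibble
#'
#' A cohort is a tibble with one row per spectrum: an `id`, a label
#' (`"mut"`, `"wt"` or `"unknown"`), the intensity vector as a list-column,
#' and the acquisition metadata needed to reconstruct each spectrum's ppm
#' axis. All pipeline verbs take and return this shape, so stages chain
#' with the pipe.
#'
#' @param id Character vector of unique spectrum identifiers.
#' @param intensities List of numeric intensity vectors (arbitrary units;
#'   negative values are allowed — baseline and noise).
#' @param params A single [acq_params()] object shared by all spectra, or a
#'   list with one per spectrum.
#' @param label Labels, recycled; case-insensitive `"mut"`, `"wt"`, or
#'   `"unknown"`.
#' @return A tibble of class `mrs_cohort`.
#' @examples
#' co <- mrs_cohort("s1", list(rnorm(1024)), acq_params(3, 1200, 1024))
#' co
#' @export
mrs_cohort <- function(id, intensities, params, label = "unknown") {
  id <- as.character(id)
  if (anyDuplicated(id)) {
    stop("Spectrum ids must be unique; duplicated: ",
         paste(unique(id[duplicated(id)]), collapse = ", "), call. = FALSE)
  }
  if (inherits(params, "acq_params")) params <- rep(list(params), length(id))
  stopifnot(length(intensities) == length(id), length(params) == length(id))
  label <- normalize_label(rep_len(label, length(id)))
  for (i in seq_along(id)) {
    check_spectrum(intensities[[i]], params[[i]], id[i])
  }
  out <- tibble::tibble(
    id = id,
    label = label,
    intensities = lapply(intensities, as.numeric),
    field_strength_T = vapply(params, `[[`, 0, "field_strength"),
    transmitter_frequency_MHz = vapply(params, `[[`, 0, "transmitter_frequency"),
    spectral_width_Hz = vapply(params, `[[`, 0, "spectral_width"),
    n_points = vapply(params, `[[`, 0L, "n_points"),
    echo_time_ms = vapply(params, `[[`, 0, "echo_time"),
    center_ppm = vapply(params, `[[`, 0, "center_ppm")
  )
  as_mrs_cohort(out)
}

as_mrs_cohort <- function(x) {
  class(x) <- unique(c("mrs_cohort", class(tibble::as_tibble(x))))
  x
}

check_spectrum <- function(intensities, params, id) {
  if (length(intensities) != params$n_points) {
    stop(sprintf(
      "Spectrum '%s': %d intensity values but n_points = %d.",
      id, length(intensities), params$n_points
    ), call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop(sprintf("Spectrum '%s': non-finite intensity values.", id),
         call. = FALSE)
  }
  invisible(TRUE)
}

normalize_label <- function(x) {
  x <- tolower(as.character(x))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- setdiff(unique(x), c("mut", "wt", "unknown"))
  if (length(bad)) {
    stop("Unknown label(s): ", paste(bad, collapse = ", "),
         " (expected mut / wt / unknown).", call. = FALSE)
  }
  x
}

#' Acquisition parameters of each cohort row
#'
#' @param cohort An `mrs_cohort` tibble.
#' @return A list of [acq_params()] objects, one per spectrum.
#' @export
cohort_params <- function(cohort) {
  purrr::pmap(
    list(cohort$field_strength_T, cohort$spectral_width_Hz,
         cohort$n_points, cohort$transmitter_frequency_MHz,
         cohort$echo_time_ms, cohort$center_ppm),
    function(b0, sw, np, f0, te, c0) {
      acq_params(b0, sw, np, transmitter_frequency = f0,
                 echo_time = te, center_ppm = c0)
    }
  )
}

#' @export
print.mrs_cohort <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<mrs_cohort> %d spectra (%d mut / %d wt / %d unknown)\n",
              n, sum(x$label == "mut"), sum(x$label == "wt"),
              sum(x$label == "unknown")))
  ledger <- attr(x, "exclusion_ledger")
  if (!is.null(ledger) && nrow(ledger)) {
    cat("  exclusions:",
        paste(sprintf("%s=%d", ledger$reason, ledger$n), collapse = ", "),
        "\n")
  }
  NextMethod()
}
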