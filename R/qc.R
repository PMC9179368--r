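#' Quality-gate amplitude thresholds
#'
#' Minimum metabolite amplitudes (vendor arbitrary units) a spectrum must
#' exceed to pass the quality gate: choline > 0.2, creatine > 0.1,
#' myo-inositol > 0 and the second creatine resonance > 0 by default.
#' Thresholds are cohort-specific conventions, not universal constants, so
#' all are configurable.
#'
#' @param cho_min,cr_min,mins_min,cr2_min Minimum amplitudes for choline
#'   (3.22 ppm), creatine (3.03 ppm), myo-inositol (3.53 ppm) and
#'   creatine 2 (3.93 ppm).
#' @param strict If `TRUE` (default) the comparison is a strict `>`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(cho_min = 0.2, cr_min = 0.1,
                          mins_min = 0, cr2_min = 0, strict = TRUE) {
  th <- c(cho = cho_min, cr = cr_min, mins = mins_min, cr2 = cr2_min)
  stopifnot(!anyNA(th))  # -Inf is allowed: it disables a criterion
  structure(list(thresholds = th, strict = isTRUE(strict)),
            class = "qc_thresholds")
}

# ppm positions at which QC amplitudes are read
qc_positions <- c(cho = 3.22, cr = 3.03, mins = 3.53, cr2 = 3.93)

#' Baseline-corrected peak amplitude at a ppm position
#'
#' Estimates a metabolite amplitude as the maximum intensity inside the
#' window `position +/- window_halfwidth` minus a local baseline, taken as
#' the median intensity over two flanking bands of width `flank_width`
#' adjacent to the window on either side. The estimate is invariant under
#' additive offsets and scales linearly with the spectrum.
#'
#' @param cohort An [mrs_cohort()] tibble.
#' @param position Peak position in ppm.
#' @param window_halfwidth Half-width of the peak window, ppm.
#' @param flank_width Width of each flanking baseline band, ppm.
#' @return Numeric vector, one amplitude per spectrum.
#' @examples
#' co <- simulate_cohort(sim_config(noise_sd = 0), 1, 0, seed = 1)
#' estimate_amplitude(co, 3.22)
#' @export
estimate_amplitude <- function(cohort, position,
                               window_halfwidth = 0.08,
                               flank_width = 0.08) {
  stopifnot(window_halfwidth > 0, flank_width > 0)
  plist <- cohort_params(cohort)
  vapply(seq_len(nrow(cohort)), function(i) {
    ax <- ppm_axis(plist[[i]])
    y <- cohort$intensities[[i]]
    inwin <- ax >= position - window_halfwidth &
      ax <= position + window_halfwidth
    if (!any(inwin)) {
      stop(sprintf(
        "Spectrum '%s': window %.3f +/- %.3f ppm lies outside the axis (%.3f..%.3f).",
        cohort$id[i], position, window_halfwidth, min(ax), max(ax)
      ), call. = FALSE)
    }
    flank <- (ax < position - window_halfwidth &
                ax >= position - window_halfwidth - flank_width) |
      (ax > position + window_halfwidth &
         ax <= position + window_halfwidth + flank_width)
    baseline <- if (any(flank)) stats::median(y[flank]) else 0
    max(y[inwin]) - baseline
  }, numeric(1))
}

#' Quality-gate a cohort
#'
#' Reads the four gate-metabolite amplitudes from every raw spectrum
#' (choline 3.22, creatine 3.03, myo-inositol 3.53, creatine 2 3.93 ppm)
#' and checks them against the thresholds. QC runs on raw, un-normalized
#' intensities because the thresholds are expressed in vendor arbitrary
#' units.
#'
#' @param cohort An [mrs_cohort()] tibble.
#' @param thresholds A [qc_thresholds()] object.
#' @param window_halfwidth,flank_width Passed to [estimate_amplitude()].
#' @return A tibble with one row per spectrum: `id`, the four amplitudes
#'   (`cho`, `cr`, `mins`, `cr2`), `qc_pass`, and `failed_criteria` (comma
#'   separated, empty when passed).
#' @examples
#' co <- simulate_cohort(sim_config(), 2, 2, seed = 1)
#' qc_cohort(co)
#' @export
qc_cohort <- function(cohort, thresholds = qc_thresholds(),
                      window_halfwidth = 0.08, flank_width = 0.08) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  amps <- vapply(
    qc_positions,
    function(p) estimate_amplitude(cohort, p, window_halfwidth, flank_width),
    numeric(nrow(cohort))
  )
  amps <- matrix(amps, nrow = nrow(cohort),
                 dimnames = list(NULL, names(qc_positions)))
  cmp <- if (thresholds$strict) `>` else `>=`
  ok <- sweep(amps, 2, thresholds$thresholds[colnames(amps)], cmp)
  failed <- apply(ok, 1, function(r) paste(colnames(amps)[!r], collapse = ","))
  tibble::tibble(
    id = cohort$id,
    cho = amps[, "cho"], cr = amps[, "cr"],
    mins = amps[, "mins"], cr2 = amps[, "cr2"],
    qc_pass = rowSums(!ok) == 0,
    failed_criteria = failed
  )
}

#' Apply predefined exclusions and the quality gate
#'
#' Reproduces cohort-assembly bookkeeping: spectra named in
#' `predefined` are removed first (reasons `"no_tumor"` or
#' `"idh_undetermined"`), then the remaining spectra are quality-gated;
#' failures are recorded as `"qc_fail"`. A spectrum named in `predefined`
#' is counted once, under its predefined reason, even if it would also
#' fail QC. Row order of the retained cohort is preserved and the counts
#' in the ledger always sum to `initial - retained`.
#'
#' @param cohort An [mrs_cohort()] tibble.
#' @param thresholds A [qc_thresholds()] object.
#' @param predefined Named character vector `id -> reason`, reasons from
#'   `"no_tumor"`, `"idh_undetermined"`.
#' @param ... Passed to [qc_cohort()].
#' @return The retained cohort, with the per-reason exclusion ledger
#'   attached (retrieve it with [exclusion_ledger()]).
#' @examples
#' co <- simulate_cohort(sim_config(), 3, 3, seed = 1)
#' kept <- apply_exclusions(co, predefined = c(sim_mut_001 = "no_tumor"))
#' exclusion_ledger(kept)
#' @export
apply_exclusions <- function(cohort, thresholds = qc_thresholds(),
                             predefined = NULL, ...) {
  allowed <- c("no_tumor", "idh_undetermined")
  if (length(predefined)) {
    bad <- setdiff(unique(predefined), allowed)
    if (length(bad)) {
      stop("Unknown exclusion reason(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    missing <- setdiff(names(predefined), cohort$id)
    if (length(missing)) {
      stop("Predefined exclusions name unknown id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  pre <- cohort$id %in% names(predefined)
  qc <- qc_cohort(cohort[!pre, , drop = FALSE], thresholds, ...)
  drop_qc <- rep(FALSE, nrow(cohort))
  drop_qc[!pre] <- !qc$qc_pass

  reasons <- c(unname(predefined), rep("qc_fail", sum(drop_qc)))
  ledger <- tibble::tibble(reason = c(allowed, "qc_fail")) |>
    dplyr::left_join(
      dplyr::count(tibble::tibble(reason = reasons), .data$reason),
      by = "reason"
    ) |>
    dplyr::mutate(n = as.integer(ifelse(is.na(.data$n), 0L, .data$n))) |>
    dplyr::filter(.data$n > 0)

  retained <- as_mrs_cohort(cohort[!(pre | drop_qc), , drop = FALSE])
  attr(retained, "exclusion_ledger") <- ledger
  retained
}

#' Exclusion ledger of a cohort
#'
#' @param cohort A cohort returned by [apply_exclusions()] (or
#'   [read_cohort()], which attaches an empty ledger).
#' @return A tibble with columns `reason` and `n`.
#' @export
exclusion_ledger <- function(cohort) {
  ledger <- attr(cohort, "exclusion_ledger")
  if (is.null(ledger)) empty_ledger() else ledger
}
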