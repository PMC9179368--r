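#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# long-format helper: one row per (spectrum, grid point)
cohort_long <- function(cohort) {
  plist <- cohort_params(cohort)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    tibble::tibble(
      id = cohort$id[i], label = cohort$label[i],
      ppm = ppm_axis(plist[[i]]),
      intensity = cohort$intensities[[i]]
    )
  })
}

#' Plot spectra
#'
#' Draws each spectrum over its ppm axis (high ppm on the left, the NMR
#' convention), colored by class label; optionally the per-class mean
#' spectrum instead of individual traces.
#'
#' @param object An `mrs_cohort` tibble.
#' @param group_mean Plot class means rather than individual spectra.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrs_cohort
#' @export
autoplot.mrs_cohort <- function(object, group_mean = FALSE, ...) {
  df <- cohort_long(object)
  if (group_mean) {
    df <- df |>
      dplyr::group_by(.data$label, .data$ppm) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          color = .data$label)) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          group = .data$id,
                                          color = .data$label)) +
      ggplot2::geom_line(alpha = 0.6)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)",
                  y = "intensity (a.u.)", color = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mrs_cohort
#' @method autoplot mrs_harmonized
#' @export
autoplot.mrs_harmonized <- function(object, group_mean = FALSE, ...) {
  grid <- attr(object, "grid")
  co <- tibble::tibble(
    id = object$id, label = object$label,
    intensities = object$intensities
  )
  df <- purrr::map_dfr(seq_len(nrow(co)), function(i) {
    tibble::tibble(id = co$id[i], label = co$label[i],
                   ppm = grid$ppm, intensity = co$intensities[[i]])
  })
  if (group_mean) {
    df <- df |>
      dplyr::group_by(.data$label, .data$ppm) |>
      dplyr::summarise(intensity = mean(.data$intensity), .groups = "drop")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          color = .data$label)) +
      ggplot2::geom_line()
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$ppm, .data$intensity,
                                          group = .data$id,
                                          color = .data$label)) +
      ggplot2::geom_line(alpha = 0.6)
  }
  p + ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)",
                  y = "normalized intensity", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a diagnostic report
#'
#' Point estimates with confidence intervals for the percentage-scale
#' statistics of a report.
#'
#' @param object An `mrs_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrs_report
#' @export
autoplot.mrs_report <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$unit == "%",
                      !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$statistic)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::xlim(0, 100) +
    ggplot2::labs(x = "estimate (%)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `mrs_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrs_roc
#' @export
autoplot.mrs_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      subtitle = sprintf("AUC = %.2f", object$auc)
    ) +
    ggplot2::theme_minimal()
}
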