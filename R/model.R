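#' Train the IDH-status classifier
#'
#' Trains the full classification stage on a harmonized training cohort:
#' the number of discriminatory features is chosen by nested
#' cross-validation (unless `k` is given), the top-k features by absolute
#' Welch t statistic are selected on the complete training data, selected
#' features are standardized with training statistics, and a linear
#' soft-margin SVM with fixed cost is fitted. The returned model carries
#' everything needed to score new harmonized spectra: feature indices and
#' ppm positions, weights, bias, scaler statistics, and the reference
#' grid it expects.
#'
#' @param x An `mrs_harmonized` training cohort (or numeric matrix with
#'   `labels`).
#' @param labels Class labels if `x` is a matrix.
#' @param config A [classifier_config()].
#' @param k Number of features; `NULL` (default) selects it by
#'   cross-validation.
#' @return An object of class `mrs_model`.
#' @examples
#' h <- harmonize_cohort(simulate_cohort(sim_config(), 8, 8, seed = 1))
#' m <- mrs_train(h, config = classifier_config(candidate_k = c(1, 2, 5)))
#' m
#' @export
mrs_train <- function(x, labels = NULL, config = classifier_config(),
                      k = NULL) {
  mat <- as_feature_matrix(x)
  if (is.null(labels) && inherits(x, "mrs_harmonized")) labels <- x$label
  labels <- normalize_label(labels)
  if (length(unique(labels)) < 2) {
    stop("Training cohort must contain both classes.", call. = FALSE)
  }

  selection <- NULL
  if (is.null(k)) {
    selection <- select_feature_count(mat$X, labels, config)
    k <- selection$k
  }
  k <- as.integer(k)
  stopifnot(k >= 1, k <= ncol(mat$X))

  if (min(table(labels)) >= 2) {
    ranked <- rank_features(mat$X, labels)
    idx <- ranked$feature[seq_len(k)]
    stat <- ranked$statistic[seq_len(k)]
  } else if (k == ncol(mat$X)) {
    # ranking needs >= 2 per class, but with every feature selected the
    # ordering is immaterial (tiny toy problems)
    idx <- seq_len(k)
    stat <- rep(NA_real_, k)
  } else {
    stop("Each class needs at least 2 spectra to rank features.",
         call. = FALSE)
  }
  fit <- svm_fit_standardized(mat$X[, idx, drop = FALSE], labels,
                              cost = config$cost)

  grid <- if (inherits(x, "mrs_harmonized")) attr(x, "grid") else NULL
  structure(
    list(
      feature_indices = idx,
      feature_ppm = if (is.null(mat$ppm)) rep(NA_real_, k) else mat$ppm[idx],
      feature_statistic = stat,
      weights = unname(fit$weights), bias = fit$bias,
      center = unname(fit$center), scale = unname(fit$scale),
      k = k, cost = config$cost,
      selection = selection, grid = grid,
      n_train = nrow(mat$X),
      class_counts = table(labels)
    ),
    class = "mrs_model"
  )
}

#' @export
print.mrs_model <- function(x, ...) {
  cat(sprintf(
    "<mrs_model> linear SVM, cost %g, %d feature(s) on %d training spectra (%s)\n",
    x$cost, x$k, x$n_train,
    paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
          collapse = ", ")
  ))
  print(tidy.mrs_model(x))
  invisible(x)
}

#' Predict IDH status for harmonized spectra
#'
#' Scores new spectra with the trained linear model. The decision score
#' is `w . x_std + b` on the standardized selected features; a spectrum
#' is called `"mut"` when its score is strictly positive (a score of
#' exactly 0 is called `"wt"`). The decision threshold is fixed at 0 — no
#' recalibration on new data.
#'
#' @param object An `mrs_model`.
#' @param newdata An `mrs_harmonized` tibble on the model's reference
#'   grid, or a numeric matrix with the same columns.
#' @param ... Unused.
#' @return A tibble with columns `id`, `score`, `label`.
#' @export
predict.mrs_model <- function(object, newdata, ...) {
  mat <- as_feature_matrix(newdata)
  if (!is.null(object$grid)) {
    if (inherits(newdata, "mrs_harmonized")) {
      g <- attr(newdata, "grid")
      if (length(g$ppm) != length(object$grid$ppm) ||
          max(abs(g$ppm - object$grid$ppm)) > 1e-9) {
        stop("New spectra are on a different reference grid; harmonize them with the model's grid first.",
             call. = FALSE)
      }
    } else if (ncol(mat$X) != length(object$grid$ppm)) {
      stop(sprintf(
        "Expected %d reference-grid columns, got %d; harmonize onto the model's grid first.",
        length(object$grid$ppm), ncol(mat$X)
      ), call. = FALSE)
    }
  }
  Xk <- mat$X[, object$feature_indices, drop = FALSE]
  Xs <- sweep(sweep(Xk, 2, object$center), 2, object$scale, `/`)
  score <- drop(Xs %*% object$weights) + object$bias
  ids <- if (inherits(newdata, "mrs_harmonized")) newdata$id
         else rownames(mat$X) %||% sprintf("s%d", seq_len(nrow(mat$X)))
  tibble::tibble(
    id = ids, score = score,
    label = ifelse(score > 0, "mut", "wt")
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected features of a trained model
#'
#' @param x An `mrs_model`.
#' @param ... Unused.
#' @return One row per selected feature: `feature`, `ppm`, `statistic`
#'   (Welch t at selection time), `weight`, `center`, `scale`.
#' @method tidy mrs_model
#' @export
tidy.mrs_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_indices,
    ppm = x$feature_ppm,
    statistic = x$feature_statistic,
    weight = x$weights,
    center = x$center,
    scale = x$scale
  )
}

#' One-row model summary
#'
#' @param x An `mrs_model`.
#' @param ... Unused.
#' @return A tibble with `k`, `cost`, `bias`, `n_train`, `n_mut`, `n_wt`,
#'   and `cv_accuracy` (mean CV accuracy at the selected k, `NA` when k
#'   was fixed by hand).
#' @method glance mrs_model
#' @export
glance.mrs_model <- function(x, ...) {
  cv_acc <- NA_real_
  if (!is.null(x$selection)) {
    ma <- x$selection$mean_accuracy
    cv_acc <- ma$mean_accuracy[ma$k == x$k]
  }
  tibble::tibble(
    k = x$k, cost = x$cost, bias = x$bias, n_train = x$n_train,
    n_mut = as.integer(x$class_counts[["mut"]]),
    n_wt = as.integer(x$class_counts[["wt"]]),
    cv_accuracy = cv_acc
  )
}

#' Save / load a trained model
#'
#' Models are stored as versioned JSON documents containing the selected
#' feature indices and ppm positions, weights, bias, scaler statistics,
#' and the reference-grid definition, so a saved model can score new data
#' after the spectra are harmonized onto its grid.
#'
#' @param model An `mrs_model`.
#' @param path Output path.
#' @return `read_model()` returns the restored `mrs_model`.
#' @export
write_model <- function(model, path) {
  grid <- model$grid
  doc <- list(
    format = "mrsidh-model", version = 1L,
    k = model$k, cost = model$cost,
    feature_indices = model$feature_indices,
    feature_ppm = model$feature_ppm,
    feature_statistic = model$feature_statistic,
    weights = model$weights, bias = model$bias,
    center = model$center, scale = model$scale,
    n_train = model$n_train,
    class_counts = as.list(model$class_counts),
    grid = if (is.null(grid)) NULL else list(
      field_strength_T = grid$params$field_strength,
      transmitter_frequency_MHz = grid$params$transmitter_frequency,
      spectral_width_Hz = grid$params$spectral_width,
      n_points = grid$params$n_points,
      center_ppm = grid$params$center_ppm,
      window = grid$window,
      anchor_ppm = grid$anchor_ppm
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mrsidh-model")) {
    stop("Not a mrsidh model file: ", path, call. = FALSE)
  }
  grid <- NULL
  if (!is.null(doc$grid)) {
    grid <- reference_grid(
      acq_params(doc$grid$field_strength_T, doc$grid$spectral_width_Hz,
                 doc$grid$n_points,
                 transmitter_frequency = doc$grid$transmitter_frequency_MHz,
                 center_ppm = doc$grid$center_ppm),
      window = doc$grid$window, anchor_ppm = doc$grid$anchor_ppm
    )
  }
  cc <- unlist(doc$class_counts)
  structure(
    list(
      feature_indices = as.integer(doc$feature_indices),
      feature_ppm = as.numeric(doc$feature_ppm),
      feature_statistic = as.numeric(doc$feature_statistic),
      weights = as.numeric(doc$weights), bias = as.numeric(doc$bias),
      center = as.numeric(doc$center), scale = as.numeric(doc$scale),
      k = as.integer(doc$k), cost = as.numeric(doc$cost),
      selection = NULL, grid = grid,
      n_train = as.integer(doc$n_train),
      class_counts = cc
    ),
    class = "mrs_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
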