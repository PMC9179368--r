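#' Rank spectral features by group difference
#'
#' Scores every reference-grid point by the absolute Welch two-sample
#' t statistic between the mutant and wild-type groups and returns the
#' features in decreasing order of that score. Welch's form is used
#' because the group variances of spectral intensities are routinely
#' unequal. A feature whose standard error is zero in both groups
#' (constant everywhere) is assigned statistic 0 and therefore ranks
#' last; ties are broken toward the lower feature index.
#'
#' @param x An `mrs_harmonized` tibble, or a numeric matrix (spectra in
#'   rows).
#' @param labels Class labels (`"mut"`/`"wt"`); taken from `x` when it is
#'   a harmonized cohort.
#' @return A tibble with columns `feature` (column index), `ppm` (when
#'   known), and `statistic` (signed Welch t, mut minus wt), ordered by
#'   decreasing `abs(statistic)`.
#' @examples
#' h <- harmonize_cohort(simulate_cohort(sim_config(), 5, 5, seed = 1))
#' head(rank_features(h))
#' @export
rank_features <- function(x, labels = NULL) {
  mat <- as_feature_matrix(x)
  if (is.null(labels) && inherits(x, "mrs_harmonized")) labels <- x$label
  labels <- normalize_label(labels)
  stopifnot(length(labels) == nrow(mat$X))
  t_stat <- welch_t_columns(mat$X, labels)
  ord <- order(-abs(t_stat), seq_along(t_stat))
  tibble::tibble(
    feature = ord,
    ppm = if (is.null(mat$ppm)) NA_real_ else mat$ppm[ord],
    statistic = t_stat[ord]
  )
}

# columnwise Welch t, mut minus wt; zero standard error -> 0 by convention
welch_t_columns <- function(X, labels) {
  i1 <- labels == "mut"
  i2 <- labels == "wt"
  if (sum(i1) < 2 || sum(i2) < 2) {
    stop("Each class needs at least 2 spectra to rank features.",
         call. = FALSE)
  }
  n1 <- sum(i1); n2 <- sum(i2)
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[i2, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[i2, , drop = FALSE], 2, stats::var)
  se <- sqrt(v1 / n1 + v2 / n2)
  t_stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  unname(t_stat)
}

as_feature_matrix <- function(x) {
  if (inherits(x, "mrs_harmonized")) {
    list(X = spectra_matrix(x), ppm = attr(x, "grid")$ppm)
  } else if (is.matrix(x)) {
    ppm <- suppressWarnings(as.numeric(colnames(x)))
    list(X = x, ppm = if (length(ppm) && !anyNA(ppm)) ppm else NULL)
  } else {
    stop("`x` must be an mrs_harmonized tibble or a numeric matrix.",
         call. = FALSE)
  }
}

#' Classifier configuration
#'
#' @param cost Soft-margin cost C of the linear SVM (default 1, the
#'   conventional library default, deliberately untuned).
#' @param candidate_k Candidate feature counts examined by
#'   cross-validation, ascending.
#' @param folds Number of stratified CV folds.
#' @param seed Seed controlling the fold assignment.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(cost = 1,
                              candidate_k = c(1, 2, 3, 5, 10, 20, 50, 100),
                              folds = 5, seed = 1) {
  stopifnot(cost > 0, folds >= 2, all(candidate_k >= 1),
            !is.unsorted(candidate_k))
  structure(
    list(cost = cost, candidate_k = as.integer(candidate_k),
         folds = as.integer(folds), seed = as.integer(seed)),
    class = "classifier_config"
  )
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, folds, seed) {
  fold_id <- integer(length(labels))
  with_seed_local(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold_id
}

#' Choose the number of discriminatory features by cross-validation
#'
#' For each candidate feature count k, runs stratified k-fold
#' cross-validation in which the feature ranking is recomputed on each
#' fold's training part only (nested selection, avoiding selection bias),
#' a linear SVM is trained on the top-k features, and held-out accuracy
#' is recorded. The selected count is the candidate with the highest mean
#' accuracy; ties go to the smallest k. Fully deterministic given the
#' config seed.
#'
#' @inheritParams rank_features
#' @param config A [classifier_config()].
#' @return A list of class `k_selection`: `k` (the winner), `cv_table`
#'   (tibble of k, fold, accuracy), `mean_accuracy` (tibble of k, mean),
#'   `folds` (folds actually used).
#' @export
select_feature_count <- function(x, labels = NULL,
                                 config = classifier_config()) {
  mat <- as_feature_matrix(x)
  if (is.null(labels) && inherits(x, "mrs_harmonized")) labels <- x$label
  labels <- normalize_label(labels)
  X <- mat$X
  p <- ncol(X)

  folds <- config$folds
  min_class <- min(table(labels))
  if (min_class < folds) {
    folds <- max(2L, as.integer(min_class))
    warning(sprintf(
      "Reducing CV folds from %d to %d (smallest class has %d spectra).",
      config$folds, folds, min_class
    ), call. = FALSE)
  }
  cand <- config$candidate_k[config$candidate_k <= p]
  if (length(cand) < length(config$candidate_k)) {
    warning(sprintf(
      "Skipping candidate feature counts > %d available features.", p
    ), call. = FALSE)
  }
  if (!length(cand)) {
    stop("No candidate feature count is <= the number of features.",
         call. = FALSE)
  }

  fold_id <- stratified_folds(labels, folds, config$seed)
  rows <- list()
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    ranked <- rank_features(X[tr, , drop = FALSE], labels[tr])
    for (k in cand) {
      idx <- ranked$feature[seq_len(k)]
      fit <- svm_fit_standardized(X[tr, idx, drop = FALSE], labels[tr],
                                  cost = config$cost)
      sc <- svm_score(fit, X[!tr, idx, drop = FALSE])
      pred <- ifelse(sc > 0, "mut", "wt")
      rows[[length(rows) + 1]] <- tibble::tibble(
        k = k, fold = f, accuracy = mean(pred == labels[!tr])
      )
    }
  }
  cv_table <- dplyr::bind_rows(rows)
  means <- cv_table |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy), .groups = "drop") |>
    dplyr::arrange(.data$k)
  best <- means$k[which.max(means$mean_accuracy)]  # ties -> smallest k
  structure(
    list(k = as.integer(best), cv_table = cv_table,
         mean_accuracy = means, folds = folds),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> k* = %d (%d-fold CV)\n", x$k, x$folds))
  print(x$mean_accuracy)
  invisible(x)
}
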