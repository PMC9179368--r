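# Linear soft-margin SVM plumbing.
#
# Fitting goes through e1071 (libsvm) with a tight termination tolerance;
# features are standardized with training statistics beforehand, so a
# fixed cost C = 1 is meaningful across data sets. The recovered primal
# weight vector is oriented so that positive decision scores mean "mut".

svm_fit_standardized <- function(X, labels, cost = 1) {
  labels <- normalize_label(labels)
  if (length(unique(labels)) < 2) {
    stop("Training data must contain both classes.", call. = FALSE)
  }
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1  # constant feature: leave centered
  Xs <- sweep(sweep(X, 2, center), 2, scl, `/`)

  y <- factor(labels, levels = c("mut", "wt"))
  fit <- e1071::svm(Xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    tolerance = 1e-8)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient (w, b) against libsvm's own decision values, then flip so that
  # positive score always means the mutant class
  dv <- attr(stats::predict(fit, Xs, decision.values = TRUE),
             "decision.values")
  s <- drop(Xs %*% w) + b
  if (stats::cor(s, drop(dv)) < 0) {
    w <- -w; b <- -b; s <- -s
  }
  pos_class <- strsplit(colnames(dv), "/", fixed = TRUE)[[1]][1]
  if (pos_class != "mut") {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b, center = center, scale = scl, cost = cost)
}

svm_score <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, `/`)
  drop(Xs %*% fit$weights) + fit$bias
}

#' Primal objective of the soft-margin linear SVM
#'
#' Evaluates `0.5 * ||w||^2 + C * sum(max(0, 1 - y_i (w . x_i + b)))`
#' with the mutant class coded +1 and wild type -1. Exposed so that
#' fitted models can be checked against direct numerical minimization.
#'
#' @param weights Weight vector.
#' @param bias Intercept.
#' @param X Feature matrix (rows = samples), on the same scale the
#'   weights refer to.
#' @param labels `"mut"` / `"wt"` labels.
#' @param cost Soft-margin cost C.
#' @return The objective value (single number).
#' @export
svm_objective <- function(weights, bias, X, labels, cost = 1) {
  y <- ifelse(normalize_label(labels) == "mut", 1, -1)
  margins <- y * (drop(X %*% weights) + bias)
  0.5 * sum(weights^2) + cost * sum(pmax(0, 1 - margins))
}
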