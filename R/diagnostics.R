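#' Confusion matrix with IDH-mutant as the positive class
#'
#' @param truth True labels (`"mut"` / `"wt"`).
#' @param estimate Predicted labels.
#' @return An object of class `mrs_confusion`: counts `tp`, `fn`, `fp`,
#'   `tn` (mut = positive).
#' @examples
#' confusion(c("mut", "mut", "wt"), c("mut", "wt", "wt"))
#' @export
confusion <- function(truth, estimate) {
  truth <- normalize_label(truth)
  estimate <- normalize_label(estimate)
  if (length(truth) != length(estimate)) {
    stop("`truth` and `estimate` must have the same length.", call. = FALSE)
  }
  if (any(truth == "unknown") || any(estimate == "unknown")) {
    stop("Labels must be 'mut' or 'wt' for a confusion matrix.",
         call. = FALSE)
  }
  mrs_confusion(
    tp = sum(truth == "mut" & estimate == "mut"),
    fn = sum(truth == "mut" & estimate == "wt"),
    fp = sum(truth == "wt" & estimate == "mut"),
    tn = sum(truth == "wt" & estimate == "wt")
  )
}

#' @rdname confusion
#' @param tp,fn,fp,tn Cell counts, for building a matrix directly.
#' @export
mrs_confusion <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(as.integer(counts)) |>
              stats::setNames(names(counts)),
            class = "mrs_confusion")
}

#' @export
print.mrs_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("mut", "wt"),
                              predicted = c("mut", "wt")))
  print(m)
  invisible(x)
}

# exact Clopper-Pearson interval via beta quantiles
clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lower, upper)
}

# logit (Wald-on-log-odds) interval for a proportion
logit_ci <- function(x, n, level = 0.95) {
  if (x == 0 || x == n) return(clopper_pearson(x, n, level))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- log(x / (n - x))
  se <- sqrt(1 / x + 1 / (n - x))
  stats::plogis(c(lo - z * se, lo + z * se))
}

#' Full diagnostic-accuracy report
#'
#' Computes, from a confusion matrix with mut as the positive class:
#' sensitivity, specificity, accuracy and disease prevalence with exact
#' Clopper–Pearson 95% confidence intervals; positive and negative
#' predictive values with logit-method intervals; and the likelihood
#' ratios LR+ = sens/(1-spec) and LR- = (1-sens)/spec with log-method
#' intervals `exp(log(LR) +/- z * SE(log LR))`, where
#' `SE(log LR+) = sqrt(1/tp - 1/n1 + 1/fp - 1/n2)` and
#' `SE(log LR-) = sqrt(1/fn - 1/n1 + 1/tn - 1/n2)`.
#'
#' A statistic whose denominator is zero is reported as `NA` with a note,
#' rather than raising, so partial reports remain possible.
#'
#' @param cm An [mrs_confusion()] object.
#' @param ci_level Confidence level (default 0.95).
#' @return A tibble of class `mrs_report` with columns `statistic`,
#'   `estimate`, `conf.low`, `conf.high`, `unit`, `note`. Proportions are
#'   reported as percentages; likelihood ratios on their natural scale.
#' @examples
#' diagnostic_report(mrs_confusion(19, 4, 12, 32))
#' @export
diagnostic_report <- function(cm, ci_level = 0.95) {
  stopifnot(inherits(cm, "mrs_confusion"))
  n1 <- cm$tp + cm$fn   # diseased (mut)
  n2 <- cm$fp + cm$tn   # non-diseased (wt)
  n <- n1 + n2
  if (n == 0) stop("Empty confusion matrix.", call. = FALSE)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)

  pct <- function(name, x, d, ci_fun, note = "") {
    if (d == 0) {
      return(tibble::tibble(statistic = name, estimate = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            unit = "%", note = "undefined: zero denominator"))
    }
    ci <- ci_fun(x, d, ci_level)
    tibble::tibble(statistic = name, estimate = 100 * x / d,
                   conf.low = 100 * ci[1], conf.high = 100 * ci[2],
                   unit = "%", note = note)
  }
  lr <- function(name, num_p, den_p, se2) {
    if (is.na(num_p) || is.na(den_p) || den_p == 0) {
      return(tibble::tibble(statistic = name, estimate = NA_real_,
                            conf.low = NA_real_, conf.high = NA_real_,
                            unit = "ratio",
                            note = "undefined: zero denominator"))
    }
    est <- num_p / den_p
    if (est == 0 || !is.finite(est) || !is.finite(se2) || se2 < 0) {
      return(tibble::tibble(statistic = name, estimate = est,
                            conf.low = NA_real_, conf.high = NA_real_,
                            unit = "ratio", note = "CI undefined (zero cell)"))
    }
    se <- sqrt(se2)
    tibble::tibble(statistic = name, estimate = est,
                   conf.low = exp(log(est) - z * se),
                   conf.high = exp(log(est) + z * se),
                   unit = "ratio", note = "log-method CI")
  }

  sens <- if (n1 > 0) cm$tp / n1 else NA_real_
  spec <- if (n2 > 0) cm$tn / n2 else NA_real_

  out <- dplyr::bind_rows(
    pct("sensitivity", cm$tp, n1, clopper_pearson),
    pct("specificity", cm$tn, n2, clopper_pearson),
    pct("accuracy", cm$tp + cm$tn, n, clopper_pearson),
    lr("lr_positive", sens, 1 - spec,
       1 / cm$tp - 1 / n1 + 1 / cm$fp - 1 / n2),
    lr("lr_negative", 1 - sens, spec,
       1 / cm$fn - 1 / n1 + 1 / cm$tn - 1 / n2),
    pct("ppv", cm$tp, cm$tp + cm$fp, logit_ci,
        note = "logit-method CI (approximate); exact methods for predictive values are not standardized"),
    pct("npv", cm$tn, cm$tn + cm$fn, logit_ci,
        note = "logit-method CI (approximate); exact methods for predictive values are not standardized"),
    pct("prevalence", n1, n, clopper_pearson)
  )
  attr(out, "confusion") <- cm
  attr(out, "ci_level") <- ci_level
  class(out) <- unique(c("mrs_report", class(out)))
  out
}

#' ROC curve and AUC by the Mann–Whitney formulation
#'
#' The AUC is the probability that a random mutant spectrum scores above
#' a random wild-type spectrum, with ties counted one half — computed
#' from rank sums, which is exactly the Mann–Whitney U statistic divided
#' by `n_mut * n_wt`. ROC points are produced at every distinct score
#' threshold.
#'
#' @param scores Numeric decision scores (higher = more mutant-like).
#' @param truth True labels (`"mut"` / `"wt"`).
#' @return A list of class `mrs_roc`: `auc` and `points`, a tibble with
#'   `threshold`, `tpr`, `fpr`.
#' @examples
#' roc_auc(c(2, 1.5, 0.3, -1), c("mut", "mut", "wt", "wt"))$auc
#' @export
roc_auc <- function(scores, truth) {
  truth <- normalize_label(truth)
  stopifnot(length(scores) == length(truth))
  pos <- truth == "mut"
  neg <- truth == "wt"
  if (!any(pos) || !any(neg)) {
    stop("Both classes are needed to compute a ROC curve.", call. = FALSE)
  }
  r <- rank(scores)                       # midranks handle ties as 1/2
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(neg))

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  points <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[neg] >= t), numeric(1))
  )
  structure(list(auc = auc, points = points), class = "mrs_roc")
}

#' @export
print.mrs_roc <- function(x, ...) {
  cat(sprintf("<mrs_roc> AUC = %.4f (%d thresholds)\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Save a diagnostic report
#'
#' Writes both a machine-readable JSON document (confusion counts plus
#' every statistic with its interval) and, optionally, an aligned text
#' table.
#'
#' @param report An `mrs_report` from [diagnostic_report()].
#' @param path Output path for the JSON document.
#' @param auc Optional AUC to include.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path, auc = NULL) {
  cm <- attr(report, "confusion")
  doc <- list(
    format = "mrsidh-report", version = 1L,
    ci_level = attr(report, "ci_level"),
    confusion = list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn),
    auc = auc,
    statistics = report
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  invisible(path)
}

#' @export
print.mrs_report <- function(x, ...) {
  cm <- attr(x, "confusion")
  if (!is.null(cm)) {
    cat(sprintf("confusion (mut positive): tp=%d fn=%d fp=%d tn=%d\n",
                cm$tp, cm$fn, cm$fp, cm$tn))
  }
  fmt <- function(e, u) ifelse(is.na(e), "    NA",
                               sprintf(if (u == "%") "%6.2f" else "%6.2f", e))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %s%s (%s-%s)\n", x$statistic[i],
                fmt(x$estimate[i], x$unit[i]),
                ifelse(x$unit[i] == "%", "%", " "),
                fmt(x$conf.low[i], x$unit[i]),
                fmt(x$conf.high[i], x$unit[i])))
  }
  invisible(x)
}
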