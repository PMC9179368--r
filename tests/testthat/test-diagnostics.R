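test_that("confusion counts treat mut as the positive class", {
  cm <- confusion(c(rep("mut", 3), rep("wt", 4)),
                  c(rep("mut", 3), rep("wt", 4)))
  expect_equal(unlist(cm[c("tp", "fn", "fp", "tn")]),
               c(tp = 3L, fn = 0L, fp = 0L, tn = 4L))

  all_wt <- confusion(c("mut", "mut", "wt"), rep("wt", 3))
  expect_equal(all_wt$tp, 0L)
  expect_equal(all_wt$fp, 0L)
  expect_equal(all_wt$fn, 2L)

  # a label vector constructed to produce (19, 4, 12, 32)
  truth <- c(rep("mut", 23), rep("wt", 44))
  pred <- c(rep("mut", 19), rep("wt", 4), rep("mut", 12), rep("wt", 32))
  cm2 <- confusion(truth, pred)
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]),
               c(tp = 19L, fn = 4L, fp = 12L, tn = 32L))

  expect_error(confusion(c("mut", "wt"), "mut"), "length")
  expect_error(confusion(c("mut", "bad"), c("wt", "wt")), "label")
})

test_that("Clopper-Pearson bounds agree with binom.test and closed forms", {
  # closed form for x = n: lower bound (alpha/2)^(1/n)
  r <- diagnostic_report(mrs_confusion(1, 0, 0, 1))
  sens <- r[r$statistic == "sensitivity", ]
  expect_equal(sens$estimate, 100)
  expect_equal(sens$conf.low, 100 * 0.025, tolerance = 1e-9)
  expect_equal(sens$conf.high, 100)

  for (case in list(c(19, 23), c(32, 44), c(51, 67), c(0, 12))) {
    ci <- mrsidh:::clopper_pearson(case[1], case[2])
    bt <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(ci, as.numeric(bt), tolerance = 1e-9)
  }
})

test_that("report statistics satisfy the exact probability identities", {
  set.seed(42)
  for (i in 1:20) {
    cm <- mrs_confusion(sample(0:15, 1), sample(0:15, 1),
                        sample(0:15, 1), sample(0:15, 1))
    n <- cm$tp + cm$fn + cm$fp + cm$tn
    if (n == 0) next
    r <- diagnostic_report(cm)
    g <- function(s) r$estimate[r$statistic == s] / 100
    if (!is.na(g("sensitivity")) && !is.na(g("specificity"))) {
      # accuracy = prev * sens + (1 - prev) * spec
      expect_equal(g("accuracy"),
                   g("prevalence") * g("sensitivity") +
                     (1 - g("prevalence")) * g("specificity"),
                   tolerance = 1e-12)
      # Bayes form of PPV
      if (!is.na(g("ppv"))) {
        rho <- g("prevalence")
        expect_equal(
          g("ppv"),
          g("sensitivity") * rho /
            (g("sensitivity") * rho + (1 - g("specificity")) * (1 - rho)),
          tolerance = 1e-12
        )
      }
    }
    # intervals contain their point estimates
    ok <- !is.na(r$estimate) & !is.na(r$conf.low)
    expect_true(all(r$conf.low[ok] <= r$estimate[ok] + 1e-9))
    expect_true(all(r$conf.high[ok] >= r$estimate[ok] - 1e-9))
  }
})

test_that("zero denominators are flagged undefined instead of erroring", {
  r <- diagnostic_report(mrs_confusion(0, 0, 3, 7))  # no diseased
  sens <- r[r$statistic == "sensitivity", ]
  expect_true(is.na(sens$estimate))
  expect_match(sens$note, "undefined")
  expect_false(is.na(r$estimate[r$statistic == "specificity"]))
})

test_that("AUC handles separation, ties, and matches pair counting", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c("mut", "mut", "wt", "wt"))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), rep(c("mut", "wt"), 3))$auc, 0.5)

  brute_auc <- function(scores, y) {
    pos <- scores[y == "mut"]; neg <- scores[y == "wt"]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(5)
  for (i in 1:10) {
    n <- sample(6:25, 1)
    y <- sample(c("mut", "wt"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(round(rnorm(n), 1))  # rounded -> ties occur
    expect_equal(roc_auc(s, y)$auc, brute_auc(s, y), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("mut", 3)), "Both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  y <- sample(c("mut", "wt"), 30, replace = TRUE, prob = c(0.4, 0.6))
  s <- rnorm(30) + (y == "mut")
  a <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(atan(s), y)$auc, a, tolerance = 1e-12)
})

test_that("ROC points trace the empirical curve", {
  roc <- roc_auc(c(0.9, 0.7, 0.4, 0.2), c("mut", "wt", "mut", "wt"))
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_true(all(diff(roc$points$fpr) >= 0))
})

test_that("report JSON export includes the confusion matrix and statistics", {
  r <- diagnostic_report(mrs_confusion(19, 4, 12, 32))
  f <- withr::local_tempfile(fileext = ".json")
  write_report(r, f, auc = 0.82)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$confusion$tp, 19)
  expect_equal(doc$auc, 0.82)
  expect_equal(nrow(doc$statistics), nrow(r))
})
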