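test_that("feature ranking matches Welch t tests and its conventions", {
  set.seed(1)
  y <- rep(c("mut", "wt"), each = 10)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 3] <- (y == "mut") + rnorm(20, sd = 0.01)  # informative column
  ranked <- rank_features(X, y)
  expect_equal(ranked$feature[1], 3)

  # statistics agree with stats::t.test (Welch) column by column
  for (j in 1:6) {
    expect_equal(
      ranked$statistic[ranked$feature == j],
      unname(stats::t.test(X[y == "mut", j], X[y == "wt", j])$statistic),
      tolerance = 1e-12
    )
  }

  # duplicated columns tie; the lower index wins
  X2 <- cbind(X[, 3], X[, 3], X[, 1])
  r2 <- rank_features(X2, y)
  expect_equal(r2$feature[1:2], c(1, 2))

  # an everywhere-constant column scores 0 and ranks last
  X3 <- cbind(X[, 3], 5, X[, 1])
  r3 <- rank_features(X3, y)
  expect_equal(r3$feature[3], 2)
  expect_equal(r3$statistic[3], 0)

  expect_error(rank_features(X[c(1, 11, 12), ], y[c(1, 11, 12)]),
               "at least 2")
})

test_that("cross-validation recovers the planted two-feature structure", {
  hits <- vapply(1:3, function(s) {
    d <- two_feature_data(seed = s)
    sel <- select_feature_count(
      d$X, d$y,
      classifier_config(candidate_k = c(1, 2, 3, 5, 10, 20, 50), seed = s)
    )
    sel$k
  }, numeric(1))
  expect_gte(sum(hits == 2), 2)
})

test_that("feature-count selection is deterministic and handles edge cases", {
  d <- two_feature_data(seed = 4, p = 10)
  cfg <- classifier_config(candidate_k = c(1, 2, 5), seed = 9)
  s1 <- select_feature_count(d$X, d$y, cfg)
  s2 <- select_feature_count(d$X, d$y, cfg)
  expect_identical(s1$k, s2$k)
  expect_equal(s1$cv_table, s2$cv_table)

  # a single candidate is returned as-is
  expect_equal(
    select_feature_count(d$X, d$y,
                         classifier_config(candidate_k = 3, seed = 1))$k,
    3L
  )
  # candidates above the feature count are skipped with a warning
  expect_warning(
    s <- select_feature_count(d$X, d$y,
                              classifier_config(candidate_k = c(2, 99),
                                                seed = 1)),
    "Skipping"
  )
  expect_equal(s$k, 2L)
  expect_error(
    suppressWarnings(select_feature_count(
      d$X, d$y, classifier_config(candidate_k = 99, seed = 1)
    )),
    "candidate"
  )
})

test_that("the separable 1-D toy reproduces the analytic max-margin solution", {
  # x = -1 (wt), +1 (mut): after standardization x_std = +/- 1/sd,
  # sd = sqrt(2); the max-margin solution has boundary 0 and scores +/- 1
  X <- matrix(c(1, -1), 2, 1)
  y <- c("mut", "wt")
  m <- mrs_train(X, y, classifier_config(cost = 100), k = 1)
  pred <- predict(m, X)
  expect_equal(pred$label, c("mut", "wt"))
  expect_equal(pred$score, c(1, -1), tolerance = 1e-6)
  expect_equal(m$bias, 0, tolerance = 1e-6)
  expect_equal(abs(m$weights), sqrt(2), tolerance = 1e-6)
})

test_that("fitted SVM attains the brute-force primal minimum", {
  for (s in 1:3) {
    set.seed(100 + s)
    n <- 14
    X <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c("mut", "wt"), length.out = n)
    X[y == "mut", 1] <- X[y == "mut", 1] + 1.2
    fit <- mrsidh:::svm_fit_standardized(X, y, cost = 1)
    Xs <- sweep(sweep(X, 2, fit$center), 2, fit$scale, `/`)
    obj_fit <- svm_objective(fit$weights, fit$bias, Xs, y, cost = 1)

    f <- function(p) svm_objective(p[1:2], p[3], Xs, y, cost = 1)
    brute <- min(vapply(1:30, function(i) {
      stats::optim(rnorm(3), f, method = "Nelder-Mead",
                   control = list(maxit = 5000, reltol = 1e-14))$value
    }, numeric(1)))
    expect_lt(abs(obj_fit - brute), 1e-4)
    # no random probe beats the fitted objective
    probes <- replicate(50, f(rnorm(3)))
    expect_true(all(obj_fit <= probes + 1e-8))
  }
})

test_that("duplicating a separable training set leaves the boundary unchanged", {
  # the hinge term enters as cost * sum over samples, so duplicating all
  # points doubles the effective cost; in the hard-margin regime (fully
  # separable, margins active, no slack) that leaves the solution fixed
  set.seed(7)
  X <- matrix(c(rnorm(10, 3, 0.3), rnorm(10, -3, 0.3)), ncol = 1)
  y <- rep(c("mut", "wt"), each = 10)
  m1 <- mrs_train(X, y, classifier_config(cost = 10), k = 1)
  m2 <- mrs_train(rbind(X, X), c(y, y), classifier_config(cost = 10), k = 1)
  s1 <- predict(m1, X)$score
  s2 <- predict(m2, X)$score
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("prediction applies the fixed zero threshold and is row-equivariant", {
  d <- two_feature_data(seed = 2, p = 10)
  m <- mrs_train(d$X, d$y, classifier_config(candidate_k = 2, seed = 1))
  pred <- predict(m, d$X)
  expect_equal(pred$label, ifelse(pred$score > 0, "mut", "wt"))

  perm <- sample(nrow(d$X))
  pred_perm <- predict(m, d$X[perm, ])
  expect_equal(pred_perm$score, pred$score[perm])

  # a score of exactly zero is called wild type
  m0 <- m
  m0$bias <- m0$bias - pred$score[1]
  expect_equal(predict(m0, d$X)$label[1], "wt")
})

test_that("the boundary direction is independent of class prevalence", {
  # under 2:1 and 1:2 class proportions (same class-conditional
  # generator), the weight of the selected feature must point the same
  # way as that feature's group contrast (Welch t): prevalence moves the
  # operating point, not the direction of the separating rule
  ok <- vapply(1:10, function(s) {
    cfg <- sim_config()
    h1 <- harmonize_cohort(simulate_cohort(cfg, 20, 10, seed = 1000 + s))
    h2 <- harmonize_cohort(simulate_cohort(cfg, 10, 20, seed = 2000 + s))
    m1 <- mrs_train(h1, config = classifier_config(), k = 1)
    m2 <- mrs_train(h2, config = classifier_config(), k = 1)
    sign(m1$weights[1]) == sign(m1$feature_statistic[1]) &&
      sign(m2$weights[1]) == sign(m2$feature_statistic[1])
  }, logical(1))
  expect_gte(sum(ok), 9)
})

test_that("models survive a JSON round trip and demand the right grid", {
  h <- harmonize_cohort(simulate_cohort(sim_config(), 8, 8, seed = 3))
  m <- mrs_train(h, config = classifier_config(candidate_k = c(1, 2),
                                               seed = 1))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$feature_indices, m$feature_indices)
  expect_equal(m2$center, m$center)
  expect_equal(predict(m2, h), predict(m, h))

  expect_error(predict(m, matrix(0, 2, 5)), "harmonize")

  td <- tidy(m)
  expect_equal(nrow(td), m$k)
  expect_true(all(c("ppm", "weight") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$k, m$k)
  expect_equal(gl$n_mut, 8L)
})
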