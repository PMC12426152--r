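test_that("the worked confusion example gives 0.5 across threshold metrics and AUC 0.75", {
  r <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$TP, 1); expect_equal(r$FP, 1)
  expect_equal(r$TN, 1); expect_equal(r$FN, 1)
  expect_equal(r$PRE, 0.5); expect_equal(r$SEN, 0.5)
  expect_equal(r$SPE, 0.5); expect_equal(r$ACC, 0.5)
  expect_equal(r$F1, 0.5)
  expect_equal(r$ROC_AUC, 0.75)
  # PR step integration by hand: thresholds .9,.6,.4,.1 give
  # (P,R) = (1,.5),(.5,.5),(2/3,1),(.5,1)
  expect_equal(r$PR_AUC, 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("perfect and inverted rankings hit the metric extremes", {
  y <- c(1, 1, 1, 0, 0)
  perfect <- compute_metrics(y, c(0.9, 0.8, 0.7, 0.2, 0.1))
  for (m in c("PRE", "SEN", "SPE", "ACC", "F1", "ROC_AUC", "PR_AUC"))
    expect_equal(perfect[[m]], 1)
  inverted <- compute_metrics(y, c(0.1, 0.2, 0.3, 0.8, 0.9))
  expect_equal(inverted$ROC_AUC, 0)
  expect_equal(inverted$SEN, 0)
})

test_that("rank-based ROC-AUC equals brute-force pair counting, ties included", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(compute_metrics(y, p)$ROC_AUC, auc_pairs(y, p))
  }
})

test_that("ROC-AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  y <- rbinom(120, 1, 0.45); p <- round(runif(120), 2)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<")))
  expect_equal(compute_metrics(y, p)$ROC_AUC, ref)
})

test_that("PR-AUC is bounded below by prevalence for a calibrated coin and is 1 when perfect", {
  y <- c(1, 0, 1, 0)
  expect_equal(compute_metrics(y, c(0.9, 0.1, 0.8, 0.2))$PR_AUC, 1)
  set.seed(3)
  y <- rbinom(400, 1, 0.3); p <- runif(400)
  expect_gt(compute_metrics(y, p)$PR_AUC, mean(y) - 0.1)
})

test_that("degenerate inputs are refused loudly", {
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.8)), "both classes")
  expect_error(compute_metrics(c(1, 0), c(1.2, 0.1)), "probabilities")
  expect_error(compute_metrics(c(1, 0, 2), c(0.1, 0.2, 0.3)), "binary")
})

test_that("cross-validation pools out-of-fold predictions and stratifies folds", {
  fix <- separable_fixture(n = 40, seed = 5)
  cv <- cross_validate(learner_spec("LR", seed = 5), fix$x, fix$y,
                       folds = 5, seed = 5)
  expect_equal(cv$pooled$F1, 1)
  expect_false(anyNA(cv$oof_probabilities))
  # fold class proportions within one member of global
  for (f in 1:5) {
    n1 <- sum(fix$y[cv$fold_id == f])
    expect_lte(abs(n1 - sum(fix$y) / 5), 1)
  }
})

test_that("leave-one-out on a tiny fixture still yields pooled metrics", {
  fix <- separable_fixture(n = 10, seed = 2)
  cv <- cross_validate(learner_spec("LR", seed = 2), fix$x, fix$y,
                       folds = 10, seed = 2)
  expect_s3_class(cv$pooled, "metric_report")
  expect_false(anyNA(cv$oof_probabilities))
})
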