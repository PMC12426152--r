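test_that("outcome labeling is the OR of the three adverse events", {
  tab <- small_cohort(n = 60, seed = 1)
  tab$hypothermia <- 0; tab$delayed_discharge <- 0; tab$delayed_awakening <- 0
  expect_true(all(label_outcome(tab) == "good"))
  tab$hypothermia[1] <- 1
  tab$delayed_awakening[2] <- 1
  tab$delayed_discharge[2] <- 1
  lab <- label_outcome(tab)
  expect_equal(lab[1], "poor")
  expect_equal(lab[2], "poor")
  expect_true(all(lab[-(1:2)] == "good"))
  tab$hypothermia[3] <- NA
  expect_error(label_outcome(tab), "binary")
  expect_error(label_outcome(tab[setdiff(names(tab), "hypothermia")]),
               "missing event flag")
})

test_that("preprocessing winsorizes at the training 1%/99% quantiles then z-scores", {
  tab <- small_cohort(n = 100, seed = 2)
  tab$alt <- as.numeric(1:100)  # known quantiles
  prep <- fit_preprocess(tab)
  s <- prep$continuous$alt
  expect_equal(s$q01, unname(quantile(1:100, 0.01, type = 7)))
  expect_equal(s$q99, unname(quantile(1:100, 0.99, type = 7)))
  x <- apply_preprocess(prep, tab)
  # training transform is centered and scaled
  cont <- c("age", "bmi", "alt", "creatinine", "crp", "nlr",
            "anesthesia_duration", "surgery_duration", "mean_hr",
            "mean_bp", "mean_rr")
  expect_lt(max(abs(colMeans(x[, cont]))), 1e-9)
  expect_lt(max(abs(apply(x[, cont], 2, sd) - 1)), 1e-9)
  # winsorized extremes map to the clamped quantiles
  w <- pmin(pmax(1:100, s$q01), s$q99)
  expect_equal(min(x[, "alt"]), (s$q01 - mean(w)) / sd(w))
  expect_equal(max(x[, "alt"]), (s$q99 - mean(w)) / sd(w))
})

test_that("categorical encodings follow the declared scheme", {
  tab <- small_cohort(n = 150, seed = 3)
  prep <- fit_preprocess(tab)
  x <- apply_preprocess(prep, tab)
  onehot <- grep("^disease_type_", colnames(x))
  expect_length(onehot, 5L)
  expect_true(all(rowSums(x[, onehot]) == 1))
  expect_true(all(x[, "asa"] %in% c(1, 2)))
  expect_true(all(x[, "surgery_type_open"] %in% c(0, 1)))
})

test_that("the fitted transform carries training statistics to new data", {
  tab <- small_cohort(n = 300, seed = 4)
  split <- stratified_split(tab, 0.8, seed = 4)
  prep <- fit_preprocess(split$train)
  x_test <- apply_preprocess(prep, split$test)
  # test columns are near-standardized but not exactly: train statistics rule
  expect_gt(max(abs(colMeans(x_test[, c("age", "crp", "nlr")]))), 1e-9)
  tab_bad <- split$test
  tab_bad$disease_type[1] <- "unknown_condition"
  expect_error(apply_preprocess(prep, tab_bad), "unseen level")
})

test_that("lasso selection returns no features for pure-noise labels", {
  hits <- vapply(1:5, function(s) {
    tab <- small_cohort(n = 300, seed = s + 100)
    x <- apply_preprocess(fit_preprocess(tab), tab)
    set.seed(s)
    y <- rbinom(nrow(x), 1, 0.45)  # labels independent of the features
    length(lasso_select(x, y, seed = s))
  }, numeric(1))
  expect_gte(sum(hits == 0), 4)
})

test_that("the stratified split reproduces the 8:2 bookkeeping exactly", {
  tab <- generate_cohort(cohort_config(n = 1128, seed = 6))
  split <- stratified_split(tab, 0.8, seed = 6)
  expect_equal(nrow(split$train), 902L)
  expect_equal(nrow(split$test), 226L)
  expect_setequal(c(split$train_idx, split$test_idx), seq_len(1128))
  expect_length(intersect(split$train_idx, split$test_idx), 0L)
  for (cls in c("poor", "good")) {
    frac_all <- sum(tab$outcome == cls)
    frac_train <- sum(split$train$outcome == cls)
    expect_lte(abs(frac_train - 0.8 * frac_all), 1)
  }
  expect_error(stratified_split(tab, 1.2), "train_fraction")
})
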