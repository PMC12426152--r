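# Toy models with analytically known attributions.
additive_fun <- function(w) {
  force(w)
  function(x) as.numeric(as.matrix(x) %*% w)
}

test_that("exact attributions match the additive-model closed form", {
  set.seed(1)
  w <- c(2, -1, 0.5, 3)
  bg <- matrix(rnorm(40 * 4), 40, 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  x <- c(f1 = 1, f2 = 2, f3 = -1, f4 = 0.5)
  res <- exact_shapley(additive_fun(w), x, bg)
  expect_equal(res$phi, w * (x - colMeans(bg)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(res$base_value, mean(bg %*% w))
})

test_that("efficiency, symmetry and null-player axioms hold on toy models", {
  set.seed(2)
  bg <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  bg[, "b"] <- bg[, "a"]  # symmetry needs exchangeable backgrounds too
  # symmetric in a and b, ignores c entirely
  f <- function(x) {
    x <- as.matrix(x)
    x[, "a"] * x[, "b"] + x[, "a"] + x[, "b"]
  }
  x <- c(a = 1.3, b = 1.3, c = 5)
  res <- exact_shapley(f, x, bg)
  expect_equal(res$phi[["a"]], res$phi[["b"]], tolerance = 1e-10)
  expect_equal(res$phi[["c"]], 0)
  expect_equal(res$base_value + sum(res$phi), f(t(x)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("efficiency holds for a fitted boosted-tree model", {
  fix <- separable_fixture(n = 100, p = 5, seed = 3)
  m <- fit_learner(learner_spec("XGBoost", seed = 3), fix$x, fix$y)
  expl <- shap_explain(m, fix$x[1:10, ], n_background = 40, seed = 3)
  pred <- predict_proba(m, fix$x[1:10, ])
  resid <- abs(expl$base_value + rowSums(expl$attributions) - pred)
  expect_lt(max(resid), 1e-6)
})

test_that("the sampled estimator converges to the exact value with P", {
  set.seed(4)
  w <- c(1, -2, 0.5, 1.5, -1, 0.3, 2)
  bg <- matrix(rnorm(25 * 7), 25, 7,
               dimnames = list(NULL, paste0("f", 1:7)))
  x <- structure(rnorm(7), names = paste0("f", 1:7))
  f <- additive_fun(w)
  exact <- exact_shapley(f, x, bg)$phi
  err2000 <- max(abs(sampled_shapley(f, x, bg, permutations = 2000,
                                     seed = 1)$phi - exact))
  out_range <- diff(range(f(bg)))
  expect_lt(err2000, 0.02 * out_range)
  # additive models are order-invariant, so convergence in P is visible
  # only with interactions
  f_int <- function(m) {
    m <- as.matrix(m)
    m[, 1] * m[, 2] + m[, 3] * m[, 4]^2 - m[, 5] * m[, 6] + m[, 7]
  }
  exact_int <- exact_shapley(f_int, x, bg)$phi
  errs <- vapply(c(10, 100, 1000), function(P) {
    median(vapply(1:9, function(s)
      median(abs(sampled_shapley(f_int, x, bg, permutations = P,
                                 seed = s)$phi - exact_int)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  # seeded reproducibility
  expect_identical(sampled_shapley(f, x, bg, permutations = 50, seed = 9),
                   sampled_shapley(f, x, bg, permutations = 50, seed = 9))
})

test_that("exact mode refuses more than 15 features", {
  bg <- matrix(rnorm(10 * 16), 10, 16)
  expect_error(exact_shapley(function(x) rowSums(as.matrix(x)),
                             rnorm(16), bg), "15 features")
})

test_that("summaries rank by mean absolute attribution with lexicographic ties", {
  expl <- structure(list(
    attributions = cbind(zeta = c(0.5, -0.5), alpha = c(0, 0),
                         beta = c(0.2, 0.2), bb = c(0.2, -0.2)),
    base_value = 0.1,
    feature_values = cbind(zeta = c(1, 2), alpha = c(3, 4), beta = c(5, 6),
                           bb = c(7, 8)),
    output_space = "probability", mode = "exact"),
    class = "shap_explanation")
  s <- shap_summary(expl)
  expect_equal(s$importance$feature, c("zeta", "bb", "beta", "alpha"))
  expect_equal(s$importance$rank, 1:4)
  expect_equal(s$importance$feature[4], "alpha")  # all-zero feature last
  dep <- shap_dependence(expl, "zeta")
  expect_equal(dep$value, c(1, 2))
  expect_equal(dep$phi, c(0.5, -0.5))
  expect_error(shap_dependence(expl, "nope"), "unknown feature")
})
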