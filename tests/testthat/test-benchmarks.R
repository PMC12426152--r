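test_that("suite covers the canonical 23 functions with their dimensions", {
  suite <- benchmark_suite()
  expect_equal(nrow(suite), 23L)
  expect_equal(suite$dim[1:13], rep(30L, 13))
  expect_equal(suite$dim[14:23], c(2L, 4L, 2L, 2L, 2L, 3L, 6L, 4L, 4L, 4L))
  expect_true(suite$noisy[7])
  expect_false(any(suite$noisy[-7]))
})

test_that("known global minima are reproduced at tabulated minimizers", {
  # exact minimizers evaluate to the known minimum; approximate literature
  # minimizers of the fixed-dimension functions come close
  expect_equal(evaluate_function(1, rep(0, 30)), 0)
  expect_equal(evaluate_function(1, rep(1, 30)), 30)
  expect_equal(evaluate_function(9, rep(0, 30)), 0)
  for (id in which(benchmark_suite()$min_exact)) {
    d <- bitterling:::benchmark_def(id)
    expect_lt(abs(d$fn(d$xmin) - d$fmin), 1e-8)
  }
  approx <- list(
    list(id = 14, x = c(-31.97833, -31.97833)),
    list(id = 16, x = c(0.08984201, -0.7126564)),
    list(id = 17, x = c(pi, 2.275)),
    list(id = 19, x = c(0.114614, 0.555649, 0.852547)),
    list(id = 20, x = c(0.20169, 0.150011, 0.476874, 0.275332, 0.311652,
                        0.6573)))
  for (a in approx) {
    fmin <- benchmark_suite(a$id)$known_minimum
    expect_lt(abs(evaluate_function(a$id, a$x) - fmin), 5e-3)
  }
  # Shekel functions: deep minimum near the first attractor
  for (id in 21:23)
    expect_lt(evaluate_function(id, c(4, 4, 4, 4)),
              benchmark_suite(id)$known_minimum + 0.15)
})

test_that("evaluation rejects unknown ids and wrong dimensionality", {
  expect_error(evaluate_function(0, 1), "unknown")
  expect_error(evaluate_function(24, 1), "unknown")
  expect_error(evaluate_function(14, c(1, 2, 3)), "fixed dimension")
  expect_error(benchmark_bounds(16, 5), "fixed dimension")
})

test_that("quartic noise comes from the caller's random stream", {
  x <- rep(0.5, 30)
  set.seed(11); v1 <- evaluate_function(7, x)
  set.seed(11); v2 <- evaluate_function(7, x)
  v3 <- evaluate_function(7, x)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  det <- sum(seq_len(30) * 0.5^4)
  expect_gte(v1, det); expect_lte(v1, det + 1)
})

test_that("benchmark runs are seed-reproducible and respect known minima", {
  r1 <- run_benchmark("ibfo", 1, dim = 5, budget = 1500, seeds = 1:3)
  r2 <- run_benchmark("ibfo", 1, dim = 5, budget = 1500, seeds = 1:3)
  expect_identical(r1$best, r2$best)
  expect_equal(nrow(r1), 3L)
  for (id in c(1, 9, 16)) {
    r <- run_benchmark("ibfo", id, budget = 1200,
                       seeds = 1:2,
                       population_size = 20)
    expect_true(all(r$best >= benchmark_suite(id)$known_minimum - 1e-9))
  }
  expect_error(run_benchmark("ibfo", 1, budget = 10, seeds = 1,
                             population_size = 30), "budget")
})

test_that("with no search budget beyond init the best equals the initial minimum", {
  obj <- function(x) sum(x^2)
  cfg <- ibfo_config(seed = 4, population_size = 12, max_iterations = 50,
                     max_evaluations = 12)
  res <- ibfo_optimize(obj, rep(-5, 3), rep(5, 3), cfg)
  expect_equal(res$evaluations, 12L)
  expect_length(res$trajectory, 1L)
  set.seed(4)
  init <- sine_chaotic_init(12, 3, rep(-5, 3), rep(5, 3))
  expect_equal(res$best_fitness, min(apply(init, 1, obj)))
})

test_that("improvement claim: IBFO is no worse than BFO on the sphere", {
  seeds <- 1:5
  med <- function(v) median(run_benchmark(v, 1, dim = 10, budget = 10000,
                                          seeds = seeds)$best)
  expect_lte(med("ibfo"), med("original_bfo"))
})
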