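# The classic 23-function optimizer benchmark suite: unimodal F1-F7,
# high-dimensional multimodal F8-F13, fixed-dimension multimodal F14-F23.
# F1-F13 accept any dimension (suite default 30); F14-F23 are fixed.

penalty_u <- function(x, a, k, m) {
  out <- numeric(length(x))
  out[x > a] <- k * (x[x > a] - a)^m
  out[x < -a] <- k * (-x[x < -a] - a)^m
  out
}

foxholes_a <- local({
  r <- c(-32, -16, 0, 16, 32)
  rbind(rep(r, 5), rep(r, each = 5))
})

kowalik_a <- c(0.1957, 0.1947, 0.1735, 0.1600, 0.0844, 0.0627,
               0.0456, 0.0342, 0.0323, 0.0235, 0.0246)
kowalik_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)

hartman3_A <- matrix(c(3, 10, 30, 0.1, 10, 35, 3, 10, 30, 0.1, 10, 35),
                     nrow = 4, byrow = TRUE)
hartman3_p <- matrix(c(0.3689, 0.1170, 0.2673,
                       0.4699, 0.4387, 0.7470,
                       0.1091, 0.8732, 0.5547,
                       0.0381, 0.5743, 0.8828), nrow = 4, byrow = TRUE)
hartman6_A <- matrix(c(10, 3, 17, 3.5, 1.7, 8,
                       0.05, 10, 17, 0.1, 8, 14,
                       3, 3.5, 1.7, 10, 17, 8,
                       17, 8, 0.05, 10, 0.1, 14), nrow = 4, byrow = TRUE)
hartman6_p <- matrix(c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886,
                       0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991,
                       0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650,
                       0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381),
                     nrow = 4, byrow = TRUE)
hartman_c <- c(1.0, 1.2, 3.0, 3.2)

shekel_a <- matrix(c(4, 4, 4, 4,  1, 1, 1, 1,  8, 8, 8, 8,  6, 6, 6, 6,
                    3, 7, 3, 7,  2, 9, 2, 9,  5, 5, 3, 3,  8, 1, 8, 1,
                    6, 2, 6, 2,  7, 3.6, 7, 3.6), ncol = 4, byrow = TRUE)
shekel_c <- c(0.1, 0.2, 0.2, 0.4, 0.4, 0.6, 0.3, 0.7, 0.5, 0.5)

shekel_fn <- function(m) {
  force(m)
  function(x) -sum(1 / (colSums((t(shekel_a[seq_len(m), ]) - x)^2) +
                          shekel_c[seq_len(m)]))
}

# Per-function definitions. `fmin` is the known global minimum; `xmin` is a
# tabulated minimizer where one is analytically exact (NULL when the
# minimizer is only known approximately); `min_exact` flags whether
# evaluating at xmin reproduces fmin to floating-point accuracy.
benchmark_defs <- function() {
  defs <- list(
    list(id = 1L, name = "sphere", dim = 30L, lb = -100, ub = 100,
         fn = function(x) sum(x^2), fmin = 0, xmin_val = 0),
    list(id = 2L, name = "schwefel_2_22", dim = 30L, lb = -10, ub = 10,
         fn = function(x) sum(abs(x)) + prod(abs(x)), fmin = 0, xmin_val = 0),
    list(id = 3L, name = "schwefel_1_2", dim = 30L, lb = -100, ub = 100,
         fn = function(x) sum(cumsum(x)^2), fmin = 0, xmin_val = 0),
    list(id = 4L, name = "schwefel_2_21", dim = 30L, lb = -100, ub = 100,
         fn = function(x) max(abs(x)), fmin = 0, xmin_val = 0),
    list(id = 5L, name = "rosenbrock", dim = 30L, lb = -30, ub = 30,
         fn = function(x) {
           d <- length(x)
           sum(100 * (x[-1] - x[-d]^2)^2 + (x[-d] - 1)^2)
         }, fmin = 0, xmin_val = 1),
    list(id = 6L, name = "step", dim = 30L, lb = -100, ub = 100,
         fn = function(x) sum(floor(x + 0.5)^2), fmin = 0, xmin_val = 0),
    list(id = 7L, name = "quartic_noise", dim = 30L, lb = -1.28, ub = 1.28,
         fn = function(x, rng = stats::runif)
           sum(seq_along(x) * x^4) + rng(1),
         fmin = 0, xmin_val = NULL, noisy = TRUE),
    list(id = 8L, name = "schwefel_2_26", dim = 30L, lb = -500, ub = 500,
         fn = function(x) -sum(x * sin(sqrt(abs(x)))),
         fmin = NA_real_, xmin_val = 420.9687462275036),
    list(id = 9L, name = "rastrigin", dim = 30L, lb = -5.12, ub = 5.12,
         fn = function(x) sum(x^2 - 10 * cos(2 * pi * x) + 10),
         fmin = 0, xmin_val = 0),
    list(id = 10L, name = "ackley", dim = 30L, lb = -32, ub = 32,
         fn = function(x)
           -20 * exp(-0.2 * sqrt(mean(x^2))) - exp(mean(cos(2 * pi * x))) +
             20 + exp(1),
         fmin = 0, xmin_val = 0),
    list(id = 11L, name = "griewank", dim = 30L, lb = -600, ub = 600,
         fn = function(x)
           sum(x^2) / 4000 - prod(cos(x / sqrt(seq_along(x)))) + 1,
         fmin = 0, xmin_val = 0),
    list(id = 12L, name = "penalized_1", dim = 30L, lb = -50, ub = 50,
         fn = function(x) {
           d <- length(x)
           y <- 1 + (x + 1) / 4
           pi / d * (10 * sin(pi * y[1])^2 +
                       sum((y[-d] - 1)^2 * (1 + 10 * sin(pi * y[-1])^2)) +
                       (y[d] - 1)^2) + sum(penalty_u(x, 10, 100, 4))
         }, fmin = 0, xmin_val = -1),
    list(id = 13L, name = "penalized_2", dim = 30L, lb = -50, ub = 50,
         fn = function(x) {
           d <- length(x)
           0.1 * (sin(3 * pi * x[1])^2 +
                    sum((x[-d] - 1)^2 * (1 + sin(3 * pi * x[-1])^2)) +
                    (x[d] - 1)^2 * (1 + sin(2 * pi * x[d])^2)) +
             sum(penalty_u(x, 5, 100, 4))
         }, fmin = NA_real_, xmin_val = 1),
    list(id = 14L, name = "foxholes", dim = 2L, lb = -65.536, ub = 65.536,
         fn = function(x) {
           s <- colSums((x - foxholes_a)^6)
           1 / (1 / 500 + sum(1 / (seq_len(25) + s)))
         }, fmin = 0.998003837794, xmin_val = NULL),
    list(id = 15L, name = "kowalik", dim = 4L, lb = -5, ub = 5,
         fn = function(x)
           sum((kowalik_a - x[1] * (kowalik_b^2 + kowalik_b * x[2]) /
                  (kowalik_b^2 + kowalik_b * x[3] + x[4]))^2),
         fmin = 0.0003074859878, xmin_val = NULL),
    list(id = 16L, name = "six_hump_camel", dim = 2L, lb = -5, ub = 5,
         fn = function(x)
           4 * x[1]^2 - 2.1 * x[1]^4 + x[1]^6 / 3 + x[1] * x[2] -
             4 * x[2]^2 + 4 * x[2]^4,
         fmin = -1.031628453489877, xmin_val = NULL),
    list(id = 17L, name = "branin", dim = 2L, lb = c(-5, 0), ub = c(10, 15),
         fn = function(x)
           (x[2] - 5.1 * x[1]^2 / (4 * pi^2) + 5 * x[1] / pi - 6)^2 +
             10 * (1 - 1 / (8 * pi)) * cos(x[1]) + 10,
         fmin = 0.39788735772973816, xmin_val = NULL),
    list(id = 18L, name = "goldstein_price", dim = 2L, lb = -2, ub = 2,
         fn = function(x) {
           x1 <- x[1]; x2 <- x[2]
           (1 + (x1 + x2 + 1)^2 *
              (19 - 14 * x1 + 3 * x1^2 - 14 * x2 + 6 * x1 * x2 + 3 * x2^2)) *
             (30 + (2 * x1 - 3 * x2)^2 *
                (18 - 32 * x1 + 12 * x1^2 + 48 * x2 - 36 * x1 * x2 +
                   27 * x2^2))
         }, fmin = 3, xmin = c(0, -1)),
    list(id = 19L, name = "hartman_3", dim = 3L, lb = 0, ub = 1,
         fn = function(x)
           -sum(hartman_c * exp(-rowSums(hartman3_A *
                                           (matrix(x, 4, 3, byrow = TRUE) -
                                              hartman3_p)^2))),
         fmin = -3.86278214782076, xmin_val = NULL),
    list(id = 20L, name = "hartman_6", dim = 6L, lb = 0, ub = 1,
         fn = function(x)
           -sum(hartman_c * exp(-rowSums(hartman6_A *
                                           (matrix(x, 4, 6, byrow = TRUE) -
                                              hartman6_p)^2))),
         fmin = -3.32236801141551, xmin_val = NULL),
    list(id = 21L, name = "shekel_5", dim = 4L, lb = 0, ub = 10,
         fn = shekel_fn(5), fmin = -10.1531996790582, xmin_val = NULL),
    list(id = 22L, name = "shekel_7", dim = 4L, lb = 0, ub = 10,
         fn = shekel_fn(7), fmin = -10.4029405668187, xmin_val = NULL),
    list(id = 23L, name = "shekel_10", dim = 4L, lb = 0, ub = 10,
         fn = shekel_fn(10), fmin = -10.5364098166920, xmin_val = NULL)
  )
  lapply(defs, function(d) {
    d$noisy <- isTRUE(d$noisy)
    if (is.null(d$xmin) && !is.null(d$xmin_val))
      d$xmin <- rep(d$xmin_val, d$dim)
    d$min_exact <- !is.null(d$xmin) && !d$noisy
    if (d$min_exact && is.na(d$fmin)) d$fmin <- d$fn(d$xmin)
    d
  })
}

.benchmark_cache <- new.env(parent = emptyenv())

benchmark_def <- function(id) {
  if (is.null(.benchmark_cache$defs)) .benchmark_cache$defs <- benchmark_defs()
  id <- as.integer(id)
  if (is.na(id) || id < 1L || id > 23L) stop("unknown benchmark function id: ", id)
  .benchmark_cache$defs[[id]]
}

#' The 23-function benchmark suite
#'
#' Returns one row per test function with its canonical dimension, bounds and
#' known global minimum. Functions 1-13 are dimension-flexible (30 by
#' default); functions 14-23 have fixed dimensionality.
#'
#' @param ids which function ids to return (default all 23).
#' @return a data.frame with columns `id`, `name`, `dim`, `lower`, `upper`,
#'   `known_minimum`, `min_exact`, `noisy`. `lower`/`upper` give the bound
#'   shared by all coordinates (Branin's asymmetric bounds are reported
#'   per-coordinate through [benchmark_bounds()]).
#' @export
benchmark_suite <- function(ids = 1:23) {
  defs <- lapply(ids, benchmark_def)
  data.frame(
    id = vapply(defs, `[[`, integer(1), "id"),
    name = vapply(defs, `[[`, character(1), "name"),
    dim = vapply(defs, `[[`, integer(1), "dim"),
    lower = vapply(defs, function(d) d$lb[1], numeric(1)),
    upper = vapply(defs, function(d) d$ub[1], numeric(1)),
    known_minimum = vapply(defs, `[[`, numeric(1), "fmin"),
    min_exact = vapply(defs, `[[`, logical(1), "min_exact"),
    noisy = vapply(defs, `[[`, logical(1), "noisy"),
    stringsAsFactors = FALSE
  )
}

#' Per-dimension bounds of a benchmark function
#'
#' @param id function id (1-23).
#' @param dim dimension; only functions 1-13 accept a non-default value.
#' @return list with numeric vectors `lower` and `upper` of length `dim`.
#' @export
benchmark_bounds <- function(id, dim = NULL) {
  d <- benchmark_def(id)
  dim <- benchmark_dim(id, dim)
  list(lower = rep_len(d$lb, dim), upper = rep_len(d$ub, dim))
}

benchmark_dim <- function(id, dim = NULL) {
  d <- benchmark_def(id)
  if (is.null(dim)) return(d$dim)
  dim <- as.integer(dim)
  if (d$id > 13L && dim != d$dim)
    stop(sprintf("function %d (%s) has fixed dimension %d", d$id, d$name, d$dim))
  if (dim < 1L) stop("dimension must be positive")
  dim
}

#' Evaluate a benchmark test function
#'
#' @param id function id (1-23).
#' @param x numeric vector; its length fixes the dimension for the
#'   dimension-flexible functions 1-13.
#' @param rng uniform random stream used only by the quartic-with-noise
#'   function (id 7); a function of `n` returning `n` U(0,1) draws. Defaults
#'   to [stats::runif] so callers control the noise through the global seed.
#' @return scalar function value.
#' @export
evaluate_function <- function(id, x, rng = stats::runif) {
  d <- benchmark_def(id)
  x <- as.numeric(x)
  dim <- benchmark_dim(id, length(x))
  if (length(x) != dim)
    stop(sprintf("function %d expects dimension %d, got %d", d$id, dim, length(x)))
  if (d$noisy) d$fn(x, rng) else d$fn(x)
}

#' Compare an optimizer against the benchmark suite
#'
#' Runs `optimizer` once per seed on a single test function under a fixed
#' objective-evaluation budget and records the best value reached. Identical
#' seeds reproduce identical results bit-for-bit on the deterministic
#' functions.
#'
#' @param optimizer either the string `"ibfo"`/`"original_bfo"` (run through
#'   [ibfo_optimize()]) or a function `(objective, lower, upper, seed,
#'   max_evaluations)` returning a list with a `best_fitness` element.
#' @param id function id.
#' @param dim problem dimension (defaults to the suite dimension).
#' @param budget total objective evaluations allowed per run; must cover at
#'   least one initial population.
#' @param seeds integer vector of seeds, one independent run each.
#' @param population_size population size used when `optimizer` is a variant
#'   name.
#' @param ... further [ibfo_config()] fields for the built-in variants.
#' @return object of class `benchmark_result`: a data.frame with one row per
#'   seed (`function_id`, `name`, `optimizer`, `seed`, `best`, `budget`).
#' @export
run_benchmark <- function(optimizer, id, dim = NULL, budget = 10000,
                          seeds = 1:5, population_size = 30, ...) {
  d <- benchmark_def(id)
  dim <- benchmark_dim(id, dim)
  if (length(seeds) < 1L) stop("at least one seed is required")
  bounds <- benchmark_bounds(id, dim)
  if (budget < population_size)
    stop("budget smaller than one population initialization")
  opt_name <- if (is.character(optimizer)) optimizer else "custom"
  best <- vapply(seeds, function(s) {
    objective <- function(x) evaluate_function(id, x)
    if (is.character(optimizer)) {
      cfg <- ibfo_config(variant = optimizer, seed = s,
                         population_size = population_size,
                         max_iterations = max(1L, ceiling(budget / population_size)),
                         max_evaluations = budget, ...)
      res <- ibfo_optimize(objective, bounds$lower, bounds$upper, cfg)
    } else {
      res <- optimizer(objective, bounds$lower, bounds$upper, seed = s,
                       max_evaluations = budget)
    }
    res$best_fitness
  }, numeric(1))
  out <- data.frame(function_id = d$id, name = d$name, optimizer = opt_name,
                    seed = seeds, best = best, budget = budget,
                    stringsAsFactors = FALSE)
  class(out) <- c("benchmark_result", class(out))
  out
}
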