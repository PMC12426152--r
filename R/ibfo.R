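# Bitterling fish optimization (BFO) and its improved variant (IBFO).
#
# The population mimics bitterling mating: each candidate moves toward the
# population best ("strongest male") and toward a fitness-proportionally
# chosen mate, with greedy acceptance. IBFO adds a sine-chaotic-map
# initialization and an occasional Gaussian random walk whose scale decays
# linearly over the run, trading early exploration for late exploitation.

#' Optimizer configuration
#'
#' @param population_size number of candidate solutions (>= 2; default 30).
#' @param max_iterations generation cap.
#' @param max_evaluations optional total objective-evaluation budget; the run
#'   stops (mid-generation if necessary) once it is exhausted.
#' @param variant `"ibfo"` (chaotic init + Gaussian walk) or
#'   `"original_bfo"` (uniform init, no walk).
#' @param walk_probability per-candidate-per-iteration probability of a
#'   Gaussian random-walk step; defaults to 0.2 for IBFO and 0 for BFO.
#' @param walk_sigma0 initial walk scale as a fraction of each coordinate's
#'   range; the scale decays as `walk_sigma0 * (1 - t/T)`.
#' @param init `"chaotic"` or `"uniform"` population initialization;
#'   defaults to the variant's convention.
#' @param seed integer seed; every stochastic draw of a run flows from it.
#' @return list of class `ibfo_config`.
#' @export
ibfo_config <- function(population_size = 30L, max_iterations = 100L,
                        max_evaluations = Inf,
                        variant = c("ibfo", "original_bfo"),
                        walk_probability = NULL, walk_sigma0 = 0.1,
                        init = NULL, seed = 1L) {
  variant <- match.arg(variant)
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("population_size must be >= 2")
  if (walk_sigma0 <= 0) stop("walk_sigma0 must be positive")
  walk_probability <- walk_probability %||%
    (if (variant == "ibfo") 0.2 else 0)
  if (walk_probability < 0 || walk_probability > 1)
    stop("walk_probability must lie in [0, 1]")
  init <- init %||% (if (variant == "ibfo") "chaotic" else "uniform")
  init <- match.arg(init, c("chaotic", "uniform"))
  structure(list(population_size = population_size,
                 max_iterations = as.integer(max_iterations),
                 max_evaluations = max_evaluations,
                 variant = variant,
                 walk_probability = walk_probability,
                 walk_sigma0 = walk_sigma0,
                 init = init, seed = as.integer(seed)),
            class = "ibfo_config")
}

#' Sine-chaotic-map population initialization
#'
#' Iterates the sine map `c_{k+1} = sin(pi * c_k)` on (0, 1), one orbit per
#' dimension from a random starting point, and affinely maps the orbit onto
#' the search bounds. Starting points (and any orbit value that collapses
#' numerically toward the absorbing point 0) are redrawn uniformly.
#'
#' @param population_size,dim population matrix shape.
#' @param lower,upper bound vectors (recycled to `dim`); must satisfy
#'   `lower < upper`.
#' @param seed optional seed; when `NULL` the current RNG state is used.
#' @return `population_size` x `dim` matrix of positions within bounds.
#' @export
sine_chaotic_init <- function(population_size, dim, lower, upper,
                              seed = NULL) {
  lower <- rep_len(lower, dim); upper <- rep_len(upper, dim)
  if (any(lower >= upper)) stop("degenerate bounds: lower >= upper")
  if (population_size * dim <= 0) stop("empty population requested")
  if (!is.null(seed)) set.seed(seed)
  c_vec <- stats::runif(dim)
  pos <- matrix(NA_real_, population_size, dim)
  for (k in seq_len(population_size)) {
    c_vec <- sine_map_next(c_vec)
    degen <- c_vec < 1e-12
    if (any(degen)) c_vec[degen] <- stats::runif(sum(degen))
    pos[k, ] <- lower + c_vec * (upper - lower)
  }
  pos
}

#' One step of the sine chaotic map
#'
#' @param c value(s) in (0, 1).
#' @return `sin(pi * c)`.
#' @export
sine_map_next <- function(c) sin(pi * c)

#' Gaussian random-walk mutation
#'
#' Adds elementwise zero-mean Gaussian noise with standard deviation
#' `sigma * (upper - lower)` per dimension, then clamps to the bounds.
#'
#' @param x position vector within bounds.
#' @param sigma walk scale as a fraction of the coordinate range (>= 0).
#' @param lower,upper bounds (recycled).
#' @return perturbed position, guaranteed within bounds.
#' @export
gaussian_walk <- function(x, sigma, lower, upper) {
  d <- length(x)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  clamp(x + stats::rnorm(d, 0, sigma * (upper - lower)), lower, upper)
}

# Fitness-proportional (roulette) index selection for a minimization
# population: weight = max(f) - f, uniform when all finite weights vanish.
roulette_min <- function(fitness) {
  w <- max(fitness[is.finite(fitness)]) - fitness
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) return(sample.int(length(fitness), 1L))
  sample.int(length(fitness), 1L, prob = w)
}

#' Run the bitterling fish optimizer
#'
#' Minimizes `objective` over a box. Candidates move toward the incumbent
#' best and a roulette-chosen mate with elementwise uniform step factors and
#' greedy acceptance; under the IBFO variant a decaying Gaussian random walk
#' is additionally applied with probability `walk_probability`. Non-finite
#' objective values are treated as rejected candidates and counted.
#'
#' @param objective function of a numeric vector returning a scalar.
#' @param lower,upper finite bound vectors.
#' @param config an [ibfo_config()].
#' @return list of class `ibfo_result`: `best_position`, `best_fitness`,
#'   `trajectory` (best-so-far after initialization and after each
#'   iteration), `evaluations`, `rejected_nonfinite`, `config`.
#' @export
ibfo_optimize <- function(objective, lower, upper, config = ibfo_config()) {
  stopifnot(inherits(config, "ibfo_config"))
  d <- max(length(lower), length(upper))
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(lower >= upper))
    stop("bounds must be finite with lower < upper")
  np <- config$population_size
  set.seed(config$seed)

  pos <- if (config$init == "chaotic") {
    sine_chaotic_init(np, d, lower, upper)
  } else {
    matrix(stats::runif(np * d), np, d) *
      rep(upper - lower, each = np) + rep(lower, each = np)
  }
  evals <- 0L
  rejected <- 0L
  eval_one <- function(x) {
    v <- objective(x)
    evals <<- evals + 1L
    if (!is.finite(v)) { rejected <<- rejected + 1L; v <- Inf }
    v
  }
  fit <- apply(pos, 1L, eval_one)
  if (all(!is.finite(fit)))
    stop("objective returned no finite value on the initial population")
  bi <- which.min(fit)
  best_x <- pos[bi, ]; best_f <- fit[bi]
  trajectory <- best_f
  tmax <- config$max_iterations

  for (t in seq_len(tmax)) {
    if (evals >= config$max_evaluations) break
    sigma_t <- config$walk_sigma0 * (1 - t / tmax)
    for (i in seq_len(np)) {
      if (evals >= config$max_evaluations) break
      m <- roulette_min(fit)
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      prop <- clamp(pos[i, ] + r1 * (best_x - pos[i, ]) +
                      r2 * (pos[m, ] - pos[i, ]), lower, upper)
      fp <- eval_one(prop)
      if (fp < fit[i]) { pos[i, ] <- prop; fit[i] <- fp }
      if (config$walk_probability > 0 && evals < config$max_evaluations &&
          stats::runif(1) < config$walk_probability) {
        walked <- gaussian_walk(pos[i, ], sigma_t, lower, upper)
        fw <- eval_one(walked)
        if (fw < fit[i]) { pos[i, ] <- walked; fit[i] <- fw }
      }
      if (fit[i] < best_f) { best_f <- fit[i]; best_x <- pos[i, ] }
    }
    trajectory <- c(trajectory, best_f)
    if (evals >= config$max_evaluations) break
  }

  structure(list(best_position = best_x, best_fitness = best_f,
                 trajectory = trajectory, evaluations = evals,
                 rejected_nonfinite = rejected, config = config),
            class = "ibfo_result")
}
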