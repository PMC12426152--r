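# Hybrid binary-real chromosome for simultaneous feature selection and
# hyperparameter optimization. The first n genes are a feature-inclusion
# bitmask; the remaining m genes live on [0,1] and decode to the learner's
# hyperparameters. GA operators (roulette selection, single-point/arithmetic
# crossover, bit-flip/Gaussian mutation) act on both parts each generation;
# the bitterling attraction move and the decaying Gaussian walk additionally
# act on the real part; survival is greedy against the parent.

#' Hyperparameter search space of a base learner
#'
#' Per-learner gene definitions with ranges and sampling scales:
#' LR: C in \[1e-3, 100\] (log-uniform), penalty in \{L1, L2\};
#' SVM: gamma in \[1e-4, 10\] (log-uniform), C in \[0.1, 1000\] (uniform);
#' BPNN: hidden width in \{16, 32, 64\}, learning rate in \[0.001, 0.1\]
#' (uniform), epochs fixed at 500;
#' XGBoost: max_depth integer in \[3, 10\], eta in \[0.01, 0.3\],
#' colsample_bytree in \[0.5, 0.9\].
#'
#' @param learner_id one of `"LR"`, `"SVM"`, `"BPNN"`, `"XGBoost"`.
#' @return list of class `search_space` with elements `learner_id`, `genes`
#'   (one list per real gene: name, type in log/linear/integer/categorical,
#'   lo/hi or values) and `fixed` (hyperparameters not searched).
#' @export
search_space <- function(learner_id) {
  learner_id <- match.arg(learner_id, LEARNER_IDS)
  genes <- switch(learner_id,
    LR = list(list(name = "C", type = "log", lo = 1e-3, hi = 100),
              list(name = "penalty", type = "categorical",
                   values = c("L1", "L2"))),
    SVM = list(list(name = "gamma", type = "log", lo = 1e-4, hi = 10),
               list(name = "C", type = "linear", lo = 0.1, hi = 1000)),
    BPNN = list(list(name = "hidden", type = "categorical",
                     values = c(16L, 32L, 64L)),
                list(name = "learning_rate", type = "linear",
                     lo = 0.001, hi = 0.1)),
    XGBoost = list(list(name = "max_depth", type = "integer", lo = 3, hi = 10),
                   list(name = "eta", type = "linear", lo = 0.01, hi = 0.3),
                   list(name = "colsample_bytree", type = "linear",
                        lo = 0.5, hi = 0.9)))
  fixed <- switch(learner_id,
    BPNN = list(epochs = 500L),
    XGBoost = list(nrounds = 100L),
    list())
  structure(list(learner_id = learner_id, genes = genes, fixed = fixed),
            class = "search_space")
}

#' Construct a hybrid chromosome
#'
#' @param mask integer/logical feature-inclusion vector (repaired to keep at
#'   least one bit set).
#' @param real_genes numeric vector on \[0,1\], one per search-space gene.
#' @param learner_id the learner the real genes decode for.
#' @return list of class `hybrid_chromosome`.
#' @export
new_chromosome <- function(mask, real_genes, learner_id) {
  mask <- as.integer(as.logical(mask))
  if (any(real_genes < 0 | real_genes > 1))
    stop("real genes must lie in [0, 1]")
  structure(list(mask = mask, real_genes = as.numeric(real_genes),
                 learner_id = match.arg(learner_id, LEARNER_IDS)),
            class = "hybrid_chromosome")
}

repair_chromosome <- function(chrom) {
  if (sum(chrom$mask) == 0L)
    chrom$mask[sample.int(length(chrom$mask), 1L)] <- 1L
  chrom
}

#' Decode a chromosome into hyperparameters and a feature set
#'
#' Log-scaled genes map as `10^(log10(lo) + g*(log10(hi) - log10(lo)))`,
#' linear genes as `lo + g*(hi - lo)`, integer genes round onto equal-width
#' buckets, and categorical genes bucket \[0,1) into equal bins.
#'
#' @param chrom a `hybrid_chromosome`.
#' @param space the learner's [search_space()].
#' @return list with `hyperparameters` (decoded + fixed) and `features`
#'   (indices of enabled mask bits).
#' @export
decode_chromosome <- function(chrom, space) {
  stopifnot(inherits(chrom, "hybrid_chromosome"),
            inherits(space, "search_space"),
            chrom$learner_id == space$learner_id)
  if (length(chrom$real_genes) != length(space$genes))
    stop("chromosome has wrong number of real genes")
  hp <- list()
  for (i in seq_along(space$genes)) {
    g <- space$genes[[i]]
    v <- chrom$real_genes[i]
    hp[[g$name]] <- switch(g$type,
      log = 10^(log10(g$lo) + v * (log10(g$hi) - log10(g$lo))),
      linear = g$lo + v * (g$hi - g$lo),
      integer = min(g$hi, g$lo + floor(v * (g$hi - g$lo + 1))),
      categorical = g$values[min(length(g$values),
                                 1L + floor(v * length(g$values)))])
  }
  list(hyperparameters = c(hp, space$fixed),
       features = which(chrom$mask == 1L))
}

#' Genetic-operator configuration
#'
#' @param crossover_prob probability of single-point/arithmetic crossover
#'   (default 0.8).
#' @param bit_flip_prob per-bit flip probability (default 0.02).
#' @param real_mutation_sd standard deviation of the Gaussian perturbation
#'   of real genes (default 0.1).
#' @param w_perf,w_sparse fitness weights of the cross-validated F1 and the
#'   normalized sparsity reciprocal `1/k` (defaults 1 and 0.05).
#' @param cv_folds folds inside the fitness (default 10).
#' @return list of class `ga_config`.
#' @export
ga_config <- function(crossover_prob = 0.8, bit_flip_prob = 0.02,
                      real_mutation_sd = 0.1, w_perf = 1, w_sparse = 0.05,
                      cv_folds = 10L) {
  stopifnot(crossover_prob >= 0, crossover_prob <= 1,
            bit_flip_prob >= 0, bit_flip_prob <= 1,
            w_perf > 0, w_sparse >= 0)
  structure(list(crossover_prob = crossover_prob,
                 bit_flip_prob = bit_flip_prob,
                 real_mutation_sd = real_mutation_sd,
                 w_perf = w_perf, w_sparse = w_sparse,
                 cv_folds = as.integer(cv_folds)),
            class = "ga_config")
}

#' Roulette-wheel selection
#'
#' Selection probability is proportional to the score after a min-shift to
#' nonnegative (scores already nonnegative are used as-is; all-equal scores
#' give uniform selection).
#'
#' @param scores numeric fitness scores (higher is better).
#' @param n how many indices to draw (with replacement).
#' @return integer indices into `scores`.
#' @export
roulette_select <- function(scores, n = 2L) {
  if (length(scores) < 2L) stop("need at least two individuals")
  w <- scores
  if (min(w) < 0) w <- w - min(w) + 1e-12
  if (sum(w) <= 0) w <- rep(1, length(w))
  sample.int(length(w), n, replace = TRUE, prob = w)
}

#' Single-point / arithmetic crossover
#'
#' With probability `crossover_prob` the binary masks exchange tails at a
#' uniform cut point and the real genes combine arithmetically as
#' `lambda*a + (1-lambda)*b` and its mirror with `lambda ~ U(0,1)`;
#' otherwise the parents are copied unchanged.
#'
#' @param a,b parent `hybrid_chromosome`s (same learner, same lengths).
#' @param config a [ga_config()].
#' @return list of two offspring chromosomes.
#' @export
crossover <- function(a, b, config = ga_config()) {
  stopifnot(a$learner_id == b$learner_id,
            length(a$mask) == length(b$mask),
            length(a$real_genes) == length(b$real_genes))
  if (stats::runif(1) < config$crossover_prob) {
    n <- length(a$mask)
    cut <- if (n > 1L) sample.int(n - 1L, 1L) else 1L
    m1 <- c(a$mask[seq_len(cut)], b$mask[-seq_len(cut)])
    m2 <- c(b$mask[seq_len(cut)], a$mask[-seq_len(cut)])
    lam <- stats::runif(1)
    r1 <- lam * a$real_genes + (1 - lam) * b$real_genes
    r2 <- (1 - lam) * a$real_genes + lam * b$real_genes
    list(new_chromosome(m1, r1, a$learner_id),
         new_chromosome(m2, r2, a$learner_id))
  } else {
    list(a, b)
  }
}

#' Bit-flip / Gaussian mutation
#'
#' Each mask bit flips independently with `bit_flip_prob`; each real gene
#' receives Gaussian noise with sd `real_mutation_sd` and is clipped to
#' \[0,1\]; an emptied mask is repaired to one random set bit.
#'
#' @param chrom a `hybrid_chromosome`.
#' @param config a [ga_config()].
#' @return mutated chromosome.
#' @export
mutate <- function(chrom, config = ga_config()) {
  flip <- stats::runif(length(chrom$mask)) < config$bit_flip_prob
  chrom$mask <- as.integer(xor(chrom$mask == 1L, flip))
  chrom$real_genes <- clamp(chrom$real_genes +
                              stats::rnorm(length(chrom$real_genes), 0,
                                           config$real_mutation_sd), 0, 1)
  repair_chromosome(chrom)
}

#' Fitness of a hybrid chromosome
#'
#' `w_perf * F1_cv + w_sparse * (1/k)` where `F1_cv` is the pooled
#' cross-validated F1 of the decoded learner on the enabled features and `k`
#' is the enabled-feature count; the sparsity reciprocal `(n/k)/n = 1/k`
#' is normalized to (0, 1] so performance stays dominant. Higher is better;
#' deterministic given `seed` (or a fixed `folds` assignment).
#'
#' @param chrom a `hybrid_chromosome`.
#' @param features full design matrix.
#' @param labels binary outcomes.
#' @param space the learner's [search_space()].
#' @param config a [ga_config()].
#' @param seed seed for fold assignment and the learner fit.
#' @param folds optional precomputed fold-id vector (overrides `cv_folds`).
#' @return scalar fitness score (attribute `f1` carries the CV F1).
#' @export
fitness_chromosome <- function(chrom, features, labels, space,
                               config = ga_config(), seed = 1L,
                               folds = NULL) {
  chrom <- repair_chromosome(chrom)
  dec <- decode_chromosome(chrom, space)
  spec <- learner_spec(chrom$learner_id, dec$hyperparameters, seed)
  x <- features[, dec$features, drop = FALSE]
  cv <- cross_validate(spec, x, labels,
                       folds = folds %||% config$cv_folds, seed = seed)
  f1 <- cv$pooled$F1
  if (is.na(f1)) f1 <- 0
  k <- length(dec$features)
  structure(config$w_perf * f1 + config$w_sparse / k, f1 = f1)
}

#' Simultaneous feature selection and hyperparameter optimization
#'
#' Evolves one population of hybrid chromosomes: each generation applies
#' roulette selection, crossover and mutation to both chromosome parts, then
#' the bitterling attraction move (toward the incumbent best and a
#' roulette-chosen mate) plus an occasional decaying Gaussian walk to the
#' real genes, and finally greedy survival against the parent. The best
#' chromosome ever evaluated is returned.
#'
#' @param features design matrix (output of [apply_preprocess()], possibly
#'   already restricted to LASSO-selected columns).
#' @param labels binary outcomes.
#' @param learner_id base learner to tune.
#' @param config a [ga_config()].
#' @param population_size,generations evolutionary budget.
#' @param walk_probability,walk_sigma0 Gaussian-walk schedule on the real
#'   genes (sd decays as `walk_sigma0 * (1 - t/T)`).
#' @param init `"chaotic"` (sine-map) or `"uniform"` initialization of the
#'   real genes.
#' @param seed integer seed; the whole run is reproducible from it.
#' @return list of class `wrapper_fit`: `best_chromosome`, `best_fitness`,
#'   `best_f1`, `decoded` (hyperparameters + feature names), `history`
#'   (best fitness per generation, monotone non-decreasing), `fold_id`.
#' @export
optimize_model <- function(features, labels, learner_id,
                           config = ga_config(), population_size = 20L,
                           generations = 15L, walk_probability = 0.2,
                           walk_sigma0 = 0.1,
                           init = c("chaotic", "uniform"), seed = 1L) {
  init <- match.arg(init)
  x <- check_features(features, labels)
  y <- as_binary01(labels)
  space <- search_space(learner_id)
  n_feat <- ncol(x)
  m <- length(space$genes)
  set.seed(seed)
  fold_id <- stratified_folds(y, config$cv_folds, seed)

  reals <- if (init == "chaotic") {
    sine_chaotic_init(population_size, m, rep(0, m), rep(1, m))
  } else {
    matrix(stats::runif(population_size * m), population_size, m)
  }
  pop <- lapply(seq_len(population_size), function(i)
    repair_chromosome(new_chromosome(stats::runif(n_feat) < 0.5,
                                     reals[i, ], learner_id)))
  score_one <- function(ch)
    fitness_chromosome(ch, x, y, space, config, seed = seed, folds = fold_id)
  scores <- vapply(pop, function(ch) as.numeric(score_one(ch)), numeric(1))
  best_i <- which.max(scores)
  best <- pop[[best_i]]; best_score <- scores[best_i]
  history <- best_score

  for (t in seq_len(generations)) {
    sigma_t <- walk_sigma0 * (1 - t / generations)
    children <- vector("list", population_size)
    for (i in seq(1L, population_size, by = 2L)) {
      par <- roulette_select(scores, 2L)
      off <- crossover(pop[[par[1]]], pop[[par[2]]], config)
      children[[i]] <- off[[1]]
      if (i + 1L <= population_size) children[[i + 1L]] <- off[[2]]
    }
    for (i in seq_len(population_size)) {
      ch <- mutate(children[[i]], config)
      mate <- pop[[roulette_select(scores, 1L)]]
      r1 <- stats::runif(m); r2 <- stats::runif(m)
      ch$real_genes <- clamp(ch$real_genes +
                               r1 * (best$real_genes - ch$real_genes) +
                               r2 * (mate$real_genes - ch$real_genes), 0, 1)
      if (walk_probability > 0 && stats::runif(1) < walk_probability)
        ch$real_genes <- clamp(ch$real_genes +
                                 stats::rnorm(m, 0, sigma_t), 0, 1)
      ch <- repair_chromosome(ch)
      s <- as.numeric(score_one(ch))
      if (s > scores[i]) { pop[[i]] <- ch; scores[i] <- s }
      if (s > best_score) { best <- ch; best_score <- s }
    }
    history <- c(history, best_score)
  }

  dec <- decode_chromosome(best, space)
  structure(list(best_chromosome = best, best_fitness = best_score,
                 best_f1 = attr(score_one(best), "f1"),
                 decoded = list(hyperparameters = dec$hyperparameters,
                                features = colnames(x)[dec$features]),
                 history = history, fold_id = fold_id,
                 learner_id = learner_id, seed = seed),
            class = "wrapper_fit")
}
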