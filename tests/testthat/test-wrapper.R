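test_that("decoding maps genes onto the declared scales and ranges", {
  sp <- search_space("LR")
  ch <- new_chromosome(c(1, 0, 1), c(0, 0), "LR")
  expect_equal(decode_chromosome(ch, sp)$hyperparameters$C, 1e-3)
  ch$real_genes <- c(0.5, 0.7)
  dec <- decode_chromosome(ch, sp)
  expect_equal(dec$hyperparameters$C, 10^(-0.5), tolerance = 1e-12)
  expect_equal(dec$hyperparameters$penalty, "L2")
  expect_equal(dec$features, c(1L, 3L))
  ch$real_genes <- c(1, 1)
  expect_equal(decode_chromosome(ch, sp)$hyperparameters$C, 100)

  # property: decoded values always lie inside their ranges, for every learner
  set.seed(31)
  for (lid in c("LR", "SVM", "BPNN", "XGBoost")) {
    space <- search_space(lid)
    m <- length(space$genes)
    for (rep in 1:50) {
      ch <- new_chromosome(rbinom(5, 1, 0.5) | c(1, 0, 0, 0, 0),
                           runif(m), lid)
      hp <- decode_chromosome(ch, space)$hyperparameters
      expect_silent(learner_spec(lid, hp))
    }
  }
})

test_that("integer and categorical genes bucket the unit interval evenly", {
  sp <- search_space("XGBoost")
  depth_of <- function(g) decode_chromosome(
    new_chromosome(1, c(g, 0.5, 0.5), "XGBoost"), sp)$hyperparameters$max_depth
  expect_equal(depth_of(0), 3)
  expect_equal(depth_of(0.999), 10)
  expect_equal(depth_of(1), 10)
  hidden_of <- function(g) decode_chromosome(
    new_chromosome(1, c(g, 0.5), "BPNN"),
    search_space("BPNN"))$hyperparameters$hidden
  expect_equal(hidden_of(0.1), 16L)
  expect_equal(hidden_of(0.5), 32L)
  expect_equal(hidden_of(0.99), 64L)
})

test_that("roulette frequencies track scores", {
  set.seed(5)
  draws <- roulette_select(c(3, 1), n = 10000)
  expect_equal(mean(draws == 1), 0.75, tolerance = 0.02)
  draws <- roulette_select(c(2, 2, 2, 2), n = 10000)
  expect_equal(as.numeric(table(draws)) / 10000, rep(0.25, 4),
               tolerance = 0.05)
  expect_true(all(roulette_select(c(0, 1, 0), n = 200) == 2))
  expect_error(roulette_select(1), "two individuals")
})

test_that("crossover keeps offspring in the parental convex hull", {
  set.seed(6)
  cfg <- ga_config()
  a <- new_chromosome(c(1, 1, 0, 0, 1), c(0.2, 0.9), "SVM")
  b <- new_chromosome(c(0, 1, 1, 0, 0), c(0.4, 0.1), "SVM")
  same <- crossover(a, a, cfg)
  expect_identical(same[[1]]$mask, a$mask)
  expect_identical(same[[1]]$real_genes, a$real_genes)
  for (rep in 1:100) {
    off <- crossover(a, b, cfg)
    for (o in off) {
      expect_true(all(o$real_genes >= pmin(a$real_genes, b$real_genes) - 1e-12))
      expect_true(all(o$real_genes <= pmax(a$real_genes, b$real_genes) + 1e-12))
      expect_true(all(o$mask %in% 0:1))
    }
  }
})

test_that("mutation matches its rates and never empties the mask", {
  ch <- new_chromosome(rep(1, 7), c(0.5, 0.5), "SVM")
  frozen <- mutate(ch, ga_config(bit_flip_prob = 0, real_mutation_sd = 0))
  expect_identical(frozen$mask, ch$mask)
  expect_identical(frozen$real_genes, ch$real_genes)

  set.seed(8)
  cfg <- ga_config()
  flips <- replicate(10000, sum(mutate(ch, cfg)$mask == 0))
  # E[flips per 7-bit chromosome] = 7 * 0.02 = 0.14
  expect_equal(mean(flips), 0.14, tolerance = 0.15)

  tiny <- new_chromosome(c(1), c(0.5, 0.5), "SVM")
  for (rep in 1:50) {
    mutated <- mutate(tiny, ga_config(bit_flip_prob = 1))
    expect_gte(sum(mutated$mask), 1)
    expect_true(all(mutated$real_genes >= 0 & mutated$real_genes <= 1))
  }
})

test_that("fitness combines CV F1 with the normalized sparsity reciprocal", {
  fix <- separable_fixture(n = 50, p = 4, seed = 10)
  sp <- search_space("LR")
  cfg <- ga_config(cv_folds = 5)
  full <- new_chromosome(rep(1, 4), c(0.8, 0.9), "LR")
  s_full <- fitness_chromosome(full, fix$x, fix$y, sp, cfg, seed = 1)
  expect_equal(attr(s_full, "f1"), 1)
  expect_equal(as.numeric(s_full), 1 + 0.05 / 4)
  solo <- new_chromosome(c(1, 0, 0, 0), c(0.8, 0.9), "LR")
  s_solo <- fitness_chromosome(solo, fix$x, fix$y, sp, cfg, seed = 1)
  expect_equal(as.numeric(s_solo), 1 + 0.05)
})

test_that("the wrapper recovers planted informative features", {
  recalls <- vapply(1:5, function(s) {
    fix <- planted_fixture(n = 150, informative = 3, noise = 7, seed = s)
    fit <- optimize_model(fix$x, fix$y, "LR",
                          config = ga_config(cv_folds = 5),
                          population_size = 12, generations = 8, seed = s)
    sel <- match(fit$decoded$features, colnames(fix$x))
    mean(fix$informative %in% sel)
  }, numeric(1))
  expect_gte(median(recalls), 0.8)
  expect_gte(mean(recalls >= 0.8), 0.6)
})

test_that("wrapper runs are elitist and reproducible", {
  fix <- planted_fixture(n = 120, informative = 2, noise = 4, seed = 3)
  fit1 <- optimize_model(fix$x, fix$y, "LR", config = ga_config(cv_folds = 4),
                         population_size = 8, generations = 5, seed = 3)
  fit2 <- optimize_model(fix$x, fix$y, "LR", config = ga_config(cv_folds = 4),
                         population_size = 8, generations = 5, seed = 3)
  expect_true(all(diff(fit1$history) >= 0))
  expect_identical(fit1$best_chromosome, fit2$best_chromosome)
  expect_identical(fit1$history, fit2$history)
})

test_that("repair guarantees a nonempty mask", {
  ch <- new_chromosome(c(1, 0), c(0.2, 0.3), "SVM")
  ch$mask <- c(0L, 0L)
  set.seed(1)
  repaired <- bitterling:::repair_chromosome(ch)
  expect_equal(sum(repaired$mask), 1)
  untouched <- bitterling:::repair_chromosome(
    new_chromosome(c(1, 1), c(0.2, 0.3), "SVM"))
  expect_equal(untouched$mask, c(1L, 1L))
})
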