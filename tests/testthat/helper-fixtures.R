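# Fixtures built in code at test time.

DRIVERS <- c("surgery_duration", "anesthesia_duration", "nlr", "crp",
             "creatinine", "bmi", "age")

# Linearly separable two-class fixture: class fully determined by x1.
separable_fixture <- function(n = 60, p = 3, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + ifelse(y == 1, 2, -2)  # wide margin
  list(x = x, y = y)
}

# Planted-signal fixture: `informative` features carry signal, the rest are
# noise; returns ground-truth indices.
planted_fixture <- function(n = 150, informative = 3, noise = 7, seed = 1,
                            strength = 1.5) {
  set.seed(seed)
  p <- informative + noise
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  eta <- x[, seq_len(informative), drop = FALSE] %*%
    rep(strength, informative)
  y <- as.integer(runif(n) < plogis(as.numeric(eta)))
  list(x = x, y = y, informative = seq_len(informative))
}

# Brute-force ROC-AUC: count concordant positive-negative pairs, half
# credit for ties. Independent oracle for the rank formulation.
auc_pairs <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

# Small cohort table built by the generator; n kept small for speed.
small_cohort <- function(n = 200, seed = 7) {
  generate_cohort(cohort_config(n = n, seed = seed))
}
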