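# Shapley-value attribution with the interventional (marginal) value
# function: v(S) is the mean model output over background rows with the
# features in S taken from the explained sample. Exact by full coalition
# enumeration up to 15 features; unbiased permutation sampling otherwise.

#' Prediction closure for a fitted model
#'
#' @param model a `bitterling_model`.
#' @return function mapping a feature matrix to positive-class
#'   probabilities, suitable for the `predict_fun` arguments below.
#' @export
predict_function <- function(model) {
  force(model)
  function(x) predict_proba(model, x)
}

coalition_values <- function(predict_fun, x_row, background, masks) {
  # masks: logical matrix (n_coalitions x k); returns v(S) per row
  b <- nrow(background); k <- ncol(background)
  vals <- numeric(nrow(masks))
  chunk <- max(1L, floor(2e5 / b))
  for (start in seq(1L, nrow(masks), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(masks))
    big <- background[rep(seq_len(b), length(idx)), , drop = FALSE]
    sel <- masks[rep(idx, each = b), , drop = FALSE]
    rep_row <- matrix(x_row, nrow(big), k, byrow = TRUE)
    big[sel] <- rep_row[sel]
    p <- predict_fun(big)
    vals[idx] <- colMeans(matrix(p, b))
  }
  vals
}

#' Exact Shapley attributions by coalition enumeration
#'
#' Enumerates all `2^k` coalitions (k <= 15) and combines marginal
#' contributions with the exact Shapley weights
#' `|S|! (k-|S|-1)! / k!`.
#'
#' @param predict_fun function mapping a feature matrix to model outputs
#'   (see [predict_function()]).
#' @param x_row named numeric vector: the sample to explain.
#' @param background matrix of background rows (same columns as `x_row`).
#' @return list with `phi` (named attribution vector) and `base_value`
#'   (mean model output over the background, i.e. v(empty set)).
#' @export
exact_shapley <- function(predict_fun, x_row, background) {
  background <- as.matrix(background)
  k <- ncol(background)
  if (length(x_row) != k) stop("sample and background disagree on feature count")
  if (k > 15L)
    stop("exact enumeration is limited to 15 features; use sampled_shapley()")
  n_coal <- 2L^k
  idx <- 0:(n_coal - 1L)
  masks <- matrix(FALSE, n_coal, k)
  for (j in seq_len(k)) masks[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0L
  v <- coalition_values(predict_fun, as.numeric(x_row), background, masks)
  sizes <- rowSums(masks)
  # weight of a coalition S not containing i; the full coalition never
  # appears as such an S, so its (undefined) weight is zeroed
  w <- numeric(n_coal)
  ok <- sizes < k
  w[ok] <- factorial(sizes[ok]) * factorial(k - sizes[ok] - 1) / factorial(k)
  phi <- numeric(k)
  for (j in seq_len(k)) {
    without <- which(!masks[, j])
    with_j <- without + bitwShiftL(1L, j - 1L)
    phi[j] <- sum(w[without] * (v[with_j] - v[without]))
  }
  names(phi) <- colnames(background) %||% names(x_row)
  list(phi = phi, base_value = v[1])
}

#' Permutation-sampled Shapley attributions
#'
#' Averages marginal contributions over `permutations` random feature
#' orderings; an unbiased estimator of the exact value, seeded.
#'
#' @inheritParams exact_shapley
#' @param permutations number of sampled orderings (P >= 1).
#' @param seed optional seed (uses the current RNG state when `NULL`).
#' @return list with `phi` and `base_value`.
#' @export
sampled_shapley <- function(predict_fun, x_row, background,
                            permutations = 200L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  background <- as.matrix(background)
  k <- ncol(background)
  if (permutations < 1L) stop("need at least one permutation")
  phi <- numeric(k)
  base <- mean(predict_fun(background))
  for (p in seq_len(permutations)) {
    ord <- sample.int(k)
    masks <- matrix(FALSE, k + 1L, k)
    for (s in seq_len(k)) masks[s + 1L, ord[seq_len(s)]] <- TRUE
    v <- coalition_values(predict_fun, as.numeric(x_row), background, masks)
    phi[ord] <- phi[ord] + diff(v)
  }
  phi <- phi / permutations
  names(phi) <- colnames(background) %||% names(x_row)
  list(phi = phi, base_value = base)
}

#' Explain a set of samples
#'
#' @param model a `bitterling_model`, or a prediction function.
#' @param X matrix of samples to explain.
#' @param background background matrix; defaults to a seeded subsample of
#'   `X` itself of at most `n_background` rows.
#' @param mode `"exact"` (coalition enumeration, k <= 15) or `"sampled"`.
#' @param permutations permutations per sample in sampled mode.
#' @param n_background background subsample size (default 100).
#' @param seed seed for background subsampling and sampled mode.
#' @return object of class `shap_explanation`: `attributions` (n x k),
#'   `base_value`, `feature_values` (= `X`), `output_space`.
#' @export
shap_explain <- function(model, X, background = NULL,
                         mode = c("exact", "sampled"), permutations = 200L,
                         n_background = 100L, seed = 1L) {
  mode <- match.arg(mode)
  predict_fun <- if (is.function(model)) model else predict_function(model)
  X <- as.matrix(X)
  set.seed(seed)
  if (is.null(background)) {
    take <- sample.int(nrow(X), min(n_background, nrow(X)))
    background <- X[take, , drop = FALSE]
  }
  background <- as.matrix(background)
  attr_mat <- matrix(NA_real_, nrow(X), ncol(X),
                     dimnames = list(NULL, colnames(X)))
  base <- NA_real_
  for (i in seq_len(nrow(X))) {
    res <- if (mode == "exact")
      exact_shapley(predict_fun, X[i, ], background)
    else sampled_shapley(predict_fun, X[i, ], background, permutations)
    attr_mat[i, ] <- res$phi
    base <- res$base_value
  }
  structure(list(attributions = attr_mat, base_value = base,
                 feature_values = X, output_space = "probability",
                 mode = mode),
            class = "shap_explanation")
}

#' Summarize an explanation
#'
#' @param explanation a `shap_explanation`.
#' @return list with `importance` (data.frame feature/mean_abs/rank, ordered
#'   by descending mean absolute attribution, ties broken lexicographically
#'   by feature name) and `summary_data` (long data.frame feature/value/phi
#'   for summary-plot rendering).
#' @export
shap_summary <- function(explanation) {
  stopifnot(inherits(explanation, "shap_explanation"))
  a <- explanation$attributions
  if (nrow(a) == 0L) stop("empty explanation")
  mean_abs <- colMeans(abs(a))
  ord <- order(-mean_abs, colnames(a))
  importance <- data.frame(feature = colnames(a)[ord],
                           mean_abs = mean_abs[ord],
                           rank = seq_along(ord), row.names = NULL,
                           stringsAsFactors = FALSE)
  summary_data <- data.frame(
    feature = rep(colnames(a), each = nrow(a)),
    value = as.vector(explanation$feature_values),
    phi = as.vector(a), stringsAsFactors = FALSE)
  list(importance = importance, summary_data = summary_data)
}

#' Dependence data for one feature
#'
#' @param explanation a `shap_explanation`.
#' @param feature feature name.
#' @return data.frame with columns `value` (feature value) and `phi`
#'   (attribution), one row per explained sample.
#' @export
shap_dependence <- function(explanation, feature) {
  stopifnot(inherits(explanation, "shap_explanation"))
  if (!feature %in% colnames(explanation$attributions))
    stop("unknown feature: ", feature)
  data.frame(value = explanation$feature_values[, feature],
             phi = explanation$attributions[, feature])
}
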