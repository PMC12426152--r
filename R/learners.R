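# The four base learners behind one fit/predict contract:
#   LR      - penalized logistic regression (glmnet; C and L1/L2 penalty)
#   SVM     - RBF support vector machine (e1071; gamma and cost, Platt-scaled
#             probabilities)
#   BPNN    - single-hidden-layer backpropagation network trained in-package
#             with full-batch Adam (hidden width, learning rate, 500 epochs)
#   XGBoost - gradient-boosted trees (xgboost; max_depth, eta,
#             colsample_bytree)
# LR and SVM expect standardized features, as produced by the cohort
# preprocessing pipeline.

LEARNER_IDS <- c("LR", "SVM", "BPNN", "XGBoost")

#' Learner specification
#'
#' @param learner_id one of `"LR"`, `"SVM"`, `"BPNN"`, `"XGBoost"`.
#' @param hyperparameters named list of decoded hyperparameters; missing
#'   entries fall back to the midpoint defaults of the search space.
#' @param seed integer seed controlling every stochastic part of the fit.
#' @return list of class `learner_spec`.
#' @export
learner_spec <- function(learner_id, hyperparameters = list(), seed = 1L) {
  learner_id <- match.arg(learner_id, LEARNER_IDS)
  hp <- utils::modifyList(default_hyperparameters(learner_id),
                          hyperparameters)
  validate_hyperparameters(learner_id, hp)
  structure(list(learner_id = learner_id, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

default_hyperparameters <- function(learner_id) {
  switch(learner_id,
    LR = list(C = 1, penalty = "L2"),
    SVM = list(gamma = 0.1, C = 1),
    BPNN = list(hidden = 32L, learning_rate = 0.01, epochs = 500L),
    XGBoost = list(max_depth = 6L, eta = 0.1, colsample_bytree = 0.8,
                   nrounds = 100L))
}

validate_hyperparameters <- function(learner_id, hp) {
  space <- search_space(learner_id)
  for (g in space$genes) {
    v <- hp[[g$name]]
    if (is.null(v)) stop("missing hyperparameter: ", g$name)
    ok <- switch(g$type,
      categorical = as.character(v) %in% as.character(g$values),
      integer = v >= g$lo && v <= g$hi && v == round(v),
      v >= g$lo && v <= g$hi)
    if (!ok) stop(sprintf("hyperparameter %s=%s outside its search range",
                          g$name, format(v)))
  }
  invisible(TRUE)
}

check_features <- function(x, y = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.null(y)) {
    y <- as_binary01(y)
    if (length(y) != nrow(x)) stop("feature/label length mismatch")
    if (length(unique(y)) < 2L) stop("single-class input: cannot fit a classifier")
  }
  x
}

#' Fit a base learner
#'
#' @param spec a [learner_spec()].
#' @param features numeric matrix (rows = patients); SVM and LR expect
#'   standardized columns.
#' @param labels binary outcomes (1 = poor recovery).
#' @return object of class `bitterling_model`.
#' @export
fit_learner <- function(spec, features, labels) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- check_features(features, labels)
  y <- as_binary01(labels)
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$learner_id,
    LR = {
      # sklearn-style mapping: penalty strength lambda = 1/(n*C).
      xx <- x
      if (ncol(xx) < 2L)  # glmnet needs >= 2 columns; a zero pad is inert
        xx <- cbind(xx, .pad = 0)
      glmnet::glmnet(xx, factor(y, levels = 0:1), family = "binomial",
                     alpha = if (identical(hp$penalty, "L1")) 1 else 0,
                     lambda = 1 / (nrow(xx) * hp$C), standardize = FALSE)
    },
    SVM = e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                     gamma = hp$gamma, cost = hp$C, probability = TRUE,
                     scale = FALSE),
    BPNN = mlp_fit(x, y, hidden = hp$hidden, learning_rate = hp$learning_rate,
                   epochs = hp$epochs, seed = spec$seed),
    XGBoost = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, colsample_bytree = hp$colsample_bytree,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    })
  structure(list(learner_id = spec$learner_id, fit = fit, spec = spec,
                 feature_names = colnames(x)),
            class = "bitterling_model")
}

#' Predict positive-class probabilities
#'
#' @param model a fitted `bitterling_model`.
#' @param features matrix whose columns match the training columns (same
#'   names, same order); a mismatch is an error, not a silent reorder.
#' @return numeric vector of probabilities of poor recovery.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "bitterling_model"))
  x <- check_features(features)
  if (!identical(colnames(x), model$feature_names))
    stop("feature columns do not match the training columns")
  p <- switch(model$learner_id,
    LR = {
      xx <- if (ncol(x) < 2L) cbind(x, .pad = 0) else x
      as.numeric(stats::predict(model$fit, xx, type = "response"))
    },
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    BPNN = mlp_predict(model$fit, x),
    XGBoost = as.numeric(stats::predict(model$fit,
                                        xgboost::xgb.DMatrix(x, nthread = 1))))
  unname(clamp(as.numeric(p), 0, 1))
}

# --- minimal single-hidden-layer network -----------------------------------
# One ReLU hidden layer, sigmoid output, cross-entropy loss, full-batch Adam.
# Written in-package so the hidden width, the learning rate and the epoch cap
# are the actual training hyperparameters the wrapper tunes.

mlp_fit <- function(x, y, hidden, learning_rate, epochs = 500L, seed = 1L) {
  set.seed(seed)
  d <- ncol(x); h <- as.integer(hidden); n <- nrow(x)
  W1 <- matrix(stats::rnorm(d * h, 0, sqrt(2 / d)), d, h)
  b1 <- numeric(h)
  W2 <- matrix(stats::rnorm(h, 0, sqrt(1 / h)), h, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(pars, function(p) p * 0)
  v <- m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    a1 <- sweep(x %*% pars$W1, 2, pars$b1, `+`)
    z1 <- pmax(a1, 0)
    logit <- as.numeric(z1 %*% pars$W2) + pars$b2
    p <- stats::plogis(logit)
    dlogit <- (p - y) / n
    grad <- list(
      W1 = t(x) %*% (((dlogit %o% as.numeric(pars$W2)) * (a1 > 0))),
      b1 = colSums((dlogit %o% as.numeric(pars$W2)) * (a1 > 0)),
      W2 = t(z1) %*% dlogit,
      b2 = sum(dlogit))
    for (nm in names(pars)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grad[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grad[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^t)
      vhat <- v[[nm]] / (1 - beta2^t)
      pars[[nm]] <- pars[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  list(pars = pars, hidden = h)
}

mlp_predict <- function(fit, x) {
  z1 <- pmax(sweep(x %*% fit$pars$W1, 2, fit$pars$b1, `+`), 0)
  stats::plogis(as.numeric(z1 %*% fit$pars$W2) + fit$pars$b2)
}
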