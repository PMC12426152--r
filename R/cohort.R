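# Cohort preprocessing: outcome labeling, Tukey outlier screening,
# 1%/99% winsorization, z-scoring, categorical encoding, LASSO lambda-1SE
# feature selection, and the stratified 8:2 split.

cohort_continuous <- c("age", "bmi", "alt", "creatinine", "crp", "nlr",
                       "anesthesia_duration", "surgery_duration",
                       "mean_hr", "mean_bp", "mean_rr")
cohort_binary <- c("gender", "heart_disease", "diabetes", "hypertension",
                   "emergency", "drug_allergy", "transfusion")
cohort_unordered <- c("disease_type", "surgery_type")
cohort_ordinal <- c("asa")
cohort_events <- c("hypothermia", "delayed_discharge", "delayed_awakening")

#' Expected cohort columns
#'
#' @return character vector of the column names a cohort table must carry.
#' @export
cohort_columns <- function() {
  c("age", "gender", "bmi", "heart_disease", "diabetes", "hypertension",
    "asa", "emergency", "drug_allergy", "alt", "creatinine", "crp", "nlr",
    "disease_type", "surgery_type", "anesthesia_duration",
    "surgery_duration", "mean_hr", "mean_bp", "mean_rr", "transfusion",
    cohort_events)
}

check_cohort <- function(table) {
  missing <- setdiff(cohort_columns(), names(table))
  if (length(missing))
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  if (anyNA(table[cohort_columns()]))
    stop("cohort table contains missing values; incomplete records are rejected")
  invisible(table)
}

#' Label the composite postoperative-recovery outcome
#'
#' A patient is labeled `poor` if at least one of the three adverse events
#' occurred: hypothermia on PACU admission, delayed PACU discharge, or
#' delayed awakening; otherwise `good`.
#'
#' @param table cohort data.frame carrying the three binary event flags.
#' @return character vector of `"poor"`/`"good"`, one per row.
#' @export
label_outcome <- function(table) {
  missing <- setdiff(cohort_events, names(table))
  if (length(missing)) stop("missing event flag: ", paste(missing, collapse = ", "))
  flags <- as.matrix(table[cohort_events])
  if (anyNA(flags) || !all(flags %in% c(0, 1)))
    stop("event flags must be binary 0/1 with no missing values")
  ifelse(rowSums(flags) >= 1, "poor", "good")
}

#' Fit the preprocessing model on the training table
#'
#' Continuous columns: Tukey fences (Q1 - 1.5 IQR, Q3 + 1.5 IQR) are
#' computed for outlier reporting, values are winsorized at the 1st/99th
#' percentiles (type-7 quantiles), then z-scored with the training mean and
#' standard deviation of the winsorized values. Unordered categoricals with
#' more than two levels are one-hot expanded; two-level ones become a single
#' indicator; ASA class is sequentially coded (I = 1, II = 2); binary flags
#' map to 0/1. The fitted model transforms any later table with the training
#' statistics (no re-fitting on test data).
#'
#' @param train cohort data.frame.
#' @return object of class `preprocess_model`.
#' @export
fit_preprocess <- function(train) {
  check_cohort(train)
  cont <- lapply(cohort_continuous, function(col) {
    x <- as.numeric(train[[col]])
    if (length(unique(x)) < 2L) stop("zero-variance continuous column: ", col)
    q <- stats::quantile(x, c(0.01, 0.25, 0.75, 0.99), type = 7, names = FALSE)
    iqr <- q[3] - q[2]
    fence <- c(q[2] - 1.5 * iqr, q[3] + 1.5 * iqr)
    w <- clamp(x, q[1], q[4])
    mu <- mean(w); sigma <- stats::sd(w)
    if (sigma <= 0) stop("zero variance after winsorization: ", col)
    list(q01 = q[1], q99 = q[4], fence_low = fence[1], fence_high = fence[2],
         n_outliers = sum(x < fence[1] | x > fence[2]), mu = mu, sigma = sigma)
  })
  names(cont) <- cohort_continuous
  cats <- lapply(cohort_unordered, function(col) {
    lev <- sort(unique(as.character(train[[col]])))
    if (length(lev) < 2L) stop("categorical column with a single level: ", col)
    lev
  })
  names(cats) <- cohort_unordered
  bins <- lapply(cohort_binary, function(col) binary_levels(train[[col]], col))
  names(bins) <- cohort_binary
  structure(list(continuous = cont, categorical = cats, binary = bins),
            class = "preprocess_model")
}

binary_levels <- function(x, col) {
  if (is.numeric(x) || is.logical(x)) {
    if (!all(x %in% c(0, 1))) stop("non-binary values in flag column: ", col)
    return(NULL)  # already 0/1
  }
  lev <- sort(unique(as.character(x)))
  if (length(lev) > 2L) stop("more than two levels in binary column: ", col)
  lev
}

#' Apply a fitted preprocessing model
#'
#' @param model a `preprocess_model` from [fit_preprocess()].
#' @param table cohort data.frame (training, test, or external).
#' @return numeric design matrix; continuous columns winsorized at the
#'   training 1%/99% quantiles and z-scored with training statistics.
#' @export
apply_preprocess <- function(model, table) {
  stopifnot(inherits(model, "preprocess_model"))
  check_cohort(table)
  n <- nrow(table)
  cols <- list()
  for (col in cohort_continuous) {
    s <- model$continuous[[col]]
    x <- as.numeric(table[[col]])
    cols[[col]] <- (clamp(x, s$q01, s$q99) - s$mu) / s$sigma
  }
  asa <- as.character(table$asa)
  if (!all(asa %in% c("I", "II"))) stop("ASA class must be I or II")
  cols[["asa"]] <- ifelse(asa == "I", 1, 2)
  for (col in cohort_binary) {
    lev <- model$binary[[col]]
    x <- table[[col]]
    if (is.null(lev)) {
      if (!all(x %in% c(0, 1))) stop("non-binary values in flag column: ", col)
      cols[[col]] <- as.numeric(x)
    } else {
      x <- as.character(x)
      if (!all(x %in% lev)) stop("unseen level in column ", col)
      cols[[col]] <- as.numeric(x == lev[2])
    }
  }
  for (col in cohort_unordered) {
    lev <- model$categorical[[col]]
    x <- as.character(table[[col]])
    if (!all(x %in% lev))
      stop("unseen level in column ", col, ": ",
           paste(setdiff(x, lev), collapse = ", "))
    if (length(lev) == 2L) {
      cols[[paste0(col, "_", lev[2])]] <- as.numeric(x == lev[2])
    } else {
      for (l in lev) cols[[paste0(col, "_", l)]] <- as.numeric(x == l)
    }
  }
  do.call(cbind, cols)
}

#' LASSO feature selection at lambda-1SE
#'
#' Fits an L1-penalized logistic path with 10-fold cross-validation (folds
#' stratified on the outcome, fixed by `seed`) and returns the features with
#' nonzero coefficients at the largest lambda whose CV loss is within one
#' standard error of the minimum.
#'
#' @param train_matrix standardized design matrix.
#' @param labels binary outcomes.
#' @param nfolds CV folds (default 10).
#' @param seed seed fixing the fold assignment.
#' @param measure CV loss: binomial `"deviance"` (default) or `"mse"`.
#' @return character vector of selected column names (possibly empty), with
#'   attributes `lambda_1se`, `lambda_min`, and `cvfit` (the cv.glmnet
#'   object).
#' @export
lasso_select <- function(train_matrix, labels, nfolds = 10L, seed = 1L,
                         measure = c("deviance", "mse")) {
  measure <- match.arg(measure)
  y <- as_binary01(labels)
  foldid <- stratified_folds(y, nfolds, seed)
  cvfit <- glmnet::cv.glmnet(train_matrix, y, family = "binomial",
                             type.measure = measure, foldid = foldid,
                             alpha = 1, standardize = FALSE)
  co <- as.matrix(stats::coef(cvfit, s = "lambda.1se"))
  selected <- rownames(co)[co[, 1] != 0 & rownames(co) != "(Intercept)"]
  structure(selected, lambda_1se = cvfit$lambda.1se,
            lambda_min = cvfit$lambda.min, cvfit = cvfit)
}

#' Outcome-stratified train/test split
#'
#' @param table data.frame with an outcome column.
#' @param train_fraction fraction assigned to training (default 0.8).
#' @param seed seed fixing the assignment.
#' @param outcome outcome column name (default `"outcome"`); created via
#'   [label_outcome()] if absent.
#' @return list with data.frames `train` and `test` plus the index vectors
#'   `train_idx` and `test_idx`; per-class training counts are
#'   `round(train_fraction * n_class)`, adjusted by at most one member so
#'   the total training size equals `round(train_fraction * n)`.
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L,
                             outcome = "outcome") {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  if (!outcome %in% names(table)) table[[outcome]] <- label_outcome(table)
  y <- table[[outcome]]
  classes <- sort(unique(as.character(y)))
  if (any(table(y) < 2L)) stop("each class needs at least 2 members")
  n_target <- round(train_fraction * nrow(table))
  per_class <- vapply(classes, function(cl)
    round(train_fraction * sum(y == cl)), numeric(1))
  # per-class rounding can miss the total by 1; adjust the largest class
  excess <- sum(per_class) - n_target
  if (excess != 0) {
    big <- which.max(per_class)
    per_class[big] <- per_class[big] - excess
  }
  set.seed(seed)
  train_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    train_idx <- c(train_idx, sort(sample(idx, per_class[i])))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(table)), train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}
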