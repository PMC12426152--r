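# Threshold and ranking metrics for binary classifiers: the
# PRE/SEN/SPE/ACC/F1/ROC-AUC/PR-AUC bundle reported for every model on every
# data split.

#' Compute the seven-metric report for one model on one split
#'
#' Confusion metrics use the given probability threshold. ROC-AUC uses the
#' rank (Mann-Whitney) formulation with half credit for ties; PR-AUC uses
#' step integration of the precision-recall curve (rectangles at each
#' achieved recall level, ties grouped).
#'
#' @param labels binary outcomes (0/1, logical, factor, or "good"/"poor").
#' @param probabilities predicted probability of the positive class.
#' @param threshold classification cut-off (default 0.5).
#' @return list of class `metric_report` with `PRE`, `SEN`, `SPE`, `ACC`,
#'   `F1`, `ROC_AUC`, `PR_AUC`, `TP`, `FP`, `TN`, `FN`, `threshold`, `n`.
#' @export
compute_metrics <- function(labels, probabilities, threshold = 0.5) {
  y <- as_binary01(labels)
  p <- as.numeric(probabilities)
  if (length(y) != length(p)) stop("labels and probabilities differ in length")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present: AUC is undefined for one-class labels")

  pred <- as.integer(p >= threshold)
  TP <- sum(pred == 1L & y == 1L); FP <- sum(pred == 1L & y == 0L)
  TN <- sum(pred == 0L & y == 0L); FN <- sum(pred == 0L & y == 1L)
  PRE <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  SEN <- TP / (TP + FN)
  SPE <- TN / (TN + FP)
  ACC <- (TP + TN) / length(y)
  F1 <- if (!is.na(PRE) && (PRE + SEN) > 0) 2 * PRE * SEN / (PRE + SEN)
        else NA_real_

  r <- rank(p, ties.method = "average")
  roc_auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pr_auc <- pr_auc_step(y, p)

  structure(list(PRE = PRE, SEN = SEN, SPE = SPE, ACC = ACC, F1 = F1,
                 ROC_AUC = roc_auc, PR_AUC = pr_auc,
                 TP = TP, FP = FP, TN = TN, FN = FN,
                 threshold = threshold, n = length(y)),
            class = "metric_report")
}

# Step integration of the PR curve: sweep thresholds from the highest score
# down (tied scores enter together) and accumulate precision * delta-recall.
pr_auc_step <- function(y, p) {
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]; p <- p[ord]
  grp_last <- which(diff(p) != 0)
  cut_idx <- c(grp_last, length(p))
  tp <- cumsum(y)[cut_idx]
  pred_pos <- cut_idx
  precision <- tp / pred_pos
  recall <- tp / sum(y)
  sum(diff(c(0, recall)) * precision)
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "metric_report (n=%d, threshold=%.3g)\n  PRE=%.4f SEN=%.4f SPE=%.4f ACC=%.4f F1=%.4f ROC-AUC=%.4f PR-AUC=%.4f\n",
    x$n, x$threshold, x$PRE, x$SEN, x$SPE, x$ACC, x$F1, x$ROC_AUC, x$PR_AUC))
  invisible(x)
}

#' Flatten metric reports to a data.frame in report column order
#'
#' @param ... `metric_report` objects (or one list of them), optionally named.
#' @return data.frame with columns model, PRE, SEN, SPE, ACC, F1, ROC_AUC,
#'   PR_AUC.
#' @export
metric_table <- function(...) {
  reports <- list(...)
  if (length(reports) == 1L && !inherits(reports[[1]], "metric_report"))
    reports <- reports[[1]]
  nm <- names(reports) %||% paste0("model_", seq_along(reports))
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(model = nm[i], PRE = r$PRE, SEN = r$SEN, SPE = r$SPE,
               ACC = r$ACC, F1 = r$F1, ROC_AUC = r$ROC_AUC,
               PR_AUC = r$PR_AUC, stringsAsFactors = FALSE)
  }))
}

#' Stratified k-fold cross-validation of a learner
#'
#' Folds are stratified on the outcome and fixed by `seed`; the pooled
#' report is computed on the concatenated out-of-fold predictions.
#'
#' @param spec a [learner_spec()].
#' @param features numeric matrix.
#' @param labels binary outcomes.
#' @param folds number of folds (default 10) or a precomputed fold-id vector.
#' @param seed seed for fold assignment and per-fold model fits.
#' @return list with `fold_reports`, `pooled` (a `metric_report`),
#'   `oof_probabilities`, `fold_id`.
#' @export
cross_validate <- function(spec, features, labels, folds = 10L, seed = 1L) {
  y <- as_binary01(labels)
  fold_id <- if (length(folds) == 1L) stratified_folds(y, folds, seed)
             else as.integer(folds)
  k <- max(fold_id)
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    tr <- fold_id != f
    if (length(unique(y[tr])) < 2L)
      stop("degenerate fold: a class is absent from the training part")
    fit <- fit_learner(spec, features[tr, , drop = FALSE], y[tr])
    oof[!tr] <- predict_proba(fit, features[!tr, , drop = FALSE])
  }
  fold_reports <- lapply(seq_len(k), function(f) {
    idx <- fold_id == f
    if (length(unique(y[idx])) < 2L) return(NULL)
    compute_metrics(y[idx], oof[idx])
  })
  list(fold_reports = fold_reports,
       pooled = compute_metrics(y, oof),
       oof_probabilities = oof, fold_id = fold_id)
}
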