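# Model-artifact persistence and the seven-feature prediction endpoint.
# An artifact bundles the fitted learner, the preprocessing statistics
# (normalization coefficients), and the selected feature names; it is saved
# as a directory with a plain-text JSON manifest plus the fitted model
# state, and round-trips to identical predictions.

#' Bundle a fitted model into an artifact
#'
#' @param model fitted `bitterling_model`.
#' @param preprocess the `preprocess_model` fitted on the training table.
#' @param selected_features feature names the model consumes, in training
#'   column order.
#' @param metadata named list (seed, config digest, free-form notes);
#'   creation time is added automatically.
#' @return list of class `model_artifact`.
#' @export
build_artifact <- function(model, preprocess, selected_features,
                           metadata = list()) {
  stopifnot(inherits(model, "bitterling_model"),
            inherits(preprocess, "preprocess_model"))
  if (!identical(model$feature_names, selected_features))
    stop("model feature names and selected_features disagree")
  metadata$created <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  structure(list(model = model, preprocess = preprocess,
                 selected_features = selected_features,
                 metadata = metadata),
            class = "model_artifact")
}

#' Save an artifact
#'
#' Writes `manifest.json` (learner, hyperparameters, selected features,
#' per-feature normalization coefficients, metadata) and `model.rds` (the
#' fitted state; boosted-tree models are stored via their raw serialization
#' so they survive the round trip).
#'
#' @param artifact a `model_artifact`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_artifact <- function(artifact, path) {
  stopifnot(inherits(artifact, "model_artifact"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  norm <- lapply(artifact$selected_features, function(f) {
    s <- artifact$preprocess$continuous[[f]]
    if (is.null(s)) list(kind = "passthrough")
    else list(kind = "continuous", q01 = s$q01, q99 = s$q99,
              mu = s$mu, sigma = s$sigma)
  })
  names(norm) <- artifact$selected_features
  manifest <- list(
    package = "bitterling",
    learner_id = artifact$model$learner_id,
    hyperparameters = artifact$model$spec$hyperparameters,
    selected_features = artifact$selected_features,
    normalization = norm,
    metadata = artifact$metadata)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  art <- artifact
  if (art$model$learner_id == "XGBoost")
    art$model$fit <- xgboost::xgb.save.raw(art$model$fit)
  saveRDS(art, file.path(path, "model.rds"))
  invisible(path)
}

#' Load an artifact
#'
#' @param path directory written by [save_artifact()].
#' @return the `model_artifact`.
#' @export
load_artifact <- function(path) {
  f <- file.path(path, "model.rds")
  if (!file.exists(f)) stop("no model artifact at ", path)
  art <- readRDS(f)
  if (art$model$learner_id == "XGBoost" && is.raw(art$model$fit))
    art$model$fit <- xgboost::xgb.load.raw(art$model$fit)
  art
}

# Physiologically plausible input ranges enforced by the prediction
# endpoint (units: min, ratio, mg/L, umol/L, kg/m2, years).
plausible_ranges <- function() {
  data.frame(
    feature = c("surgery_duration", "anesthesia_duration", "nlr", "crp",
                "creatinine", "bmi", "age"),
    lo = c(10, 15, 0.1, 0, 10, 10, 18),
    hi = c(900, 960, 50, 300, 1000, 60, 100),
    stringsAsFactors = FALSE)
}

#' Predict postoperative recovery from feature values
#'
#' Applies the artifact's stored normalization (training winsor bounds and
#' z-score coefficients) to the supplied values, runs the fitted model, and
#' thresholds the poor-recovery probability at 0.5. Values outside the
#' documented physiological ranges are refused with a warning unless
#' `override = TRUE`.
#'
#' @param artifact a `model_artifact` whose selected features are continuous
#'   clinical variables (the seven-feature model in the default pipeline).
#' @param values named numeric vector/list supplying every selected feature.
#' @param override allow out-of-range inputs.
#' @return list with `class` (`"poor"`/`"good"`), `probability` (of poor
#'   recovery), and the normalized `inputs`.
#' @export
predict_recovery <- function(artifact, values, override = FALSE) {
  stopifnot(inherits(artifact, "model_artifact"))
  values <- unlist(values)
  missing <- setdiff(artifact$selected_features, names(values))
  if (length(missing))
    stop("missing feature values: ", paste(missing, collapse = ", "))
  values <- values[artifact$selected_features]
  rng <- plausible_ranges()
  for (f in intersect(names(values), rng$feature)) {
    r <- rng[rng$feature == f, ]
    if (values[[f]] < r$lo || values[[f]] > r$hi) {
      msg <- sprintf("%s = %g outside plausible range [%g, %g]",
                     f, values[[f]], r$lo, r$hi)
      if (!override) { warning(msg); stop("refusing implausible input (use override = TRUE)") }
      warning(msg, " (override in effect)")
    }
  }
  z <- vapply(artifact$selected_features, function(f) {
    s <- artifact$preprocess$continuous[[f]]
    if (is.null(s))
      stop("prediction endpoint supports continuous features only; '",
           f, "' has no stored normalization")
    (clamp(values[[f]], s$q01, s$q99) - s$mu) / s$sigma
  }, numeric(1))
  x <- matrix(z, 1L, dimnames = list(NULL, artifact$selected_features))
  p <- predict_proba(artifact$model, x)
  list(class = if (p >= 0.5) "poor" else "good", probability = p,
       inputs = z)
}
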