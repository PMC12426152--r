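`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Stratified fold assignment
#'
#' Assigns each observation to one of `k` folds so that class proportions are
#' preserved within one member per fold. Assignment is deterministic given
#' `seed`.
#'
#' @param y binary outcome vector (0/1, logical, or two-level factor).
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1:k`, same length as `y`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as_binary01(y)
  n <- length(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than observations")
  folds <- integer(n)
  set.seed(seed)
  offset <- 0L
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

# Coerce an outcome vector to 0/1 integers; errors on anything non-binary.
as_binary01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) {
    if (all(y %in% c("good", "poor"))) y <- as.integer(y == "poor")
    else stop("character labels must be 'good'/'poor'")
  }
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  y
}

# Simple stderr logger used by the CLI.
cli_log <- function(..., file = NULL) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(..., collapse = ""))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}
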