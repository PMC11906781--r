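# Normalization and scaling for LC-MS feature tables:
# median-by-row -> PQN (control-group reference spectrum) -> log10 ->
# autoscale, with the fitted constants kept so the identical transform can
# be applied to held-out samples.

#' Median-by-row normalization
#'
#' Divides every sample (row) by its own median intensity, so each output
#' row has median 1. Corrects gross per-sample intensity differences.
#'
#' @param X Strictly positive samples-by-features matrix.
#' @return List with `X` (normalized matrix) and `row_medians`.
#' @export
median_row_normalize <- function(X) {
  X <- as.matrix(X)
  med <- apply(X, 1, stats::median)
  bad <- which(med <= 0)
  if (length(bad)) {
    nm <- rownames(X)[bad] %||% as.character(bad)
    stop("non-positive row median for sample(s): ",
         paste(utils::head(nm, 5), collapse = ", "), call. = FALSE)
  }
  list(X = X / med, row_medians = med)
}

#' Probabilistic quotient normalization
#'
#' Uses the element-wise median spectrum of the reference class as the
#' reference `r`; each sample is divided by the median of its intensity
#' quotients against `r`, which estimates the sample's dilution factor.
#' Features with a zero reference value are excluded from the quotient
#' median with a warning.
#'
#' @param X Strictly positive samples-by-features matrix.
#' @param classes Class label per sample (length `nrow(X)`). Ignored when
#'   `reference` is supplied.
#' @param reference_class Label of the class whose median spectrum is the
#'   reference (default `"CTRL"`).
#' @param reference Optional precomputed reference spectrum (e.g. from a
#'   training fold) overriding the class-median computation.
#' @return List with `X` (normalized), `reference` (r_j) and `factors`
#'   (per-sample quotient medians s_i).
#' @export
pqn_normalize <- function(X, classes = NULL, reference_class = "CTRL",
                          reference = NULL) {
  X <- as.matrix(X)
  if (is.null(reference)) {
    if (is.null(classes)) stop("supply classes or a reference spectrum", call. = FALSE)
    stopifnot(length(classes) == nrow(X))
    ref_rows <- which(classes == reference_class)
    if (length(ref_rows) == 0L) {
      stop("no samples in reference class '", reference_class, "'", call. = FALSE)
    }
    reference <- apply(X[ref_rows, , drop = FALSE], 2, stats::median)
  }
  if (all(reference == 0)) stop("all-zero reference spectrum", call. = FALSE)
  usable <- reference > 0
  if (any(!usable)) {
    warning(sum(!usable), " feature(s) with zero reference value excluded ",
            "from quotient medians")
  }
  Q <- sweep(X[, usable, drop = FALSE], 2, reference[usable], "/")
  s <- apply(Q, 1, stats::median)
  if (any(s <= 0)) stop("non-positive quotient median; check input", call. = FALSE)
  list(X = X / s, reference = reference, factors = s)
}

#' Log10 transform
#'
#' @param X Matrix; `X + offset` must be strictly positive.
#' @param offset Non-negative pseudo-intensity added before the log.
#' @return `log10(X + offset)`.
#' @export
log_transform <- function(X, offset = 0) {
  stopifnot(offset >= 0)
  X <- as.matrix(X)
  if (any(X + offset <= 0)) {
    stop("log transform undefined: values <= -offset present", call. = FALSE)
  }
  log10(X + offset)
}

#' Autoscale (unit-variance scale) a matrix
#'
#' Centers every feature to mean 0 and scales to standard deviation 1
#' (sample SD, n-1 denominator). Constant features are dropped with a
#' warning and recorded in the returned state.
#'
#' @param X Samples-by-features matrix.
#' @return List with `X` (autoscaled), `means`, `sds`, and `dropped`
#'   (indices of constant features removed).
#' @export
autoscale <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  # numerically constant columns: SD indistinguishable from rounding noise
  tol <- 1e-10 * pmax(1, abs(mu))
  dropped <- which(sd_ <= tol | !is.finite(sd_))
  if (length(dropped) == ncol(X)) stop("all features are constant", call. = FALSE)
  if (length(dropped)) {
    warning(length(dropped), " constant feature(s) dropped before autoscaling")
    X <- X[, -dropped, drop = FALSE]
    mu <- mu[-dropped]; sd_ <- sd_[-dropped]
  }
  list(X = sweep(sweep(X, 2, mu, "-"), 2, sd_, "/"),
       means = mu, sds = sd_, dropped = dropped)
}

#' Invert an autoscaling transform
#'
#' @param X Autoscaled matrix.
#' @param means,sds Constants returned by [autoscale()].
#' @return Matrix on the original scale.
#' @export
autoscale_invert <- function(X, means, sds) {
  sweep(sweep(as.matrix(X), 2, sds, "*"), 2, means, "+")
}

#' Preprocessing recipe
#'
#' Bundles the switches of the normalization sequence. Stages are applied in
#' the fixed order row-median -> PQN -> log10 -> autoscale, each at most
#' once.
#'
#' @param do_row_median Apply median-by-row normalization first.
#' @param do_pqn Apply probabilistic quotient normalization.
#' @param pqn_reference_class Reference class for PQN.
#' @param log_offset Pseudo-intensity for the log10 step; `NULL` selects
#'   half the smallest non-zero intensity when zeros are present
#'   (`zero_policy = "offset"`), else 0.
#' @param do_autoscale Apply unit-variance scaling.
#' @param zero_policy `"offset"` (default) or `"error"` on zero intensities.
#' @return Object of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(do_row_median = TRUE, do_pqn = TRUE,
                              pqn_reference_class = "CTRL",
                              log_offset = NULL, do_autoscale = TRUE,
                              zero_policy = c("offset", "error")) {
  zero_policy <- match.arg(zero_policy)
  if (!is.null(log_offset)) stopifnot(log_offset >= 0)
  structure(list(do_row_median = do_row_median, do_pqn = do_pqn,
                 pqn_reference_class = pqn_reference_class,
                 log_offset = log_offset, do_autoscale = do_autoscale,
                 zero_policy = zero_policy),
            class = "preprocess_recipe")
}

#' Run the full preprocessing sequence
#'
#' Applies the recipe stages in order and records every fitted constant
#' (row medians, PQN reference and factors, log offset, column means/SDs) in
#' a state object so the same transform can be replayed on new samples with
#' [apply_preprocess()].
#'
#' @param X Non-negative samples-by-features matrix.
#' @param classes Class labels (required when PQN is enabled without a
#'   stored reference).
#' @param recipe A [preprocess_recipe()].
#' @return List with `X` (processed matrix) and `state`
#'   (class `preprocess_state`).
#' @export
preprocess <- function(X, classes = NULL, recipe = preprocess_recipe()) {
  stopifnot(inherits(recipe, "preprocess_recipe"))
  X <- as.matrix(X)
  if (any(X < 0)) stop("negative intensities in feature table", call. = FALSE)
  offset <- recipe$log_offset
  if (any(X == 0)) {
    if (recipe$zero_policy == "error") stop("zero intensities present", call. = FALSE)
    if (is.null(offset)) offset <- min(X[X > 0]) / 2
    X <- X + offset
  } else if (is.null(offset)) offset <- 0
  state <- list(recipe = recipe, offset = offset,
                row_medians = NULL, pqn_reference = NULL, pqn_factors = NULL,
                col_means = NULL, col_sds = NULL, dropped = integer(0))
  if (recipe$do_row_median) {
    rm_ <- median_row_normalize(X)
    X <- rm_$X; state$row_medians <- rm_$row_medians
  }
  if (recipe$do_pqn) {
    pq <- pqn_normalize(X, classes, recipe$pqn_reference_class)
    X <- pq$X; state$pqn_reference <- pq$reference; state$pqn_factors <- pq$factors
  }
  X <- log10(X)
  if (recipe$do_autoscale) {
    au <- autoscale(X)
    X <- au$X
    state$col_means <- au$means; state$col_sds <- au$sds
    state$dropped <- au$dropped
  }
  class(state) <- "preprocess_state"
  list(X = X, state = state)
}

#' Apply a fitted preprocessing state to new samples
#'
#' Replays the normalization sequence on held-out data using only constants
#' estimated from the training data (PQN reference spectrum, log offset,
#' column means and SDs). Row-median and PQN factors are per-sample by
#' construction and are recomputed for the new rows; nothing is re-fit from
#' the new data at the feature level, preventing leakage across
#' cross-validation folds.
#'
#' @param state A `preprocess_state` from [preprocess()].
#' @param X New non-negative samples-by-features matrix (all original
#'   features, same order).
#' @return Processed matrix on the training scale.
#' @export
apply_preprocess <- function(state, X) {
  stopifnot(inherits(state, "preprocess_state"))
  recipe <- state$recipe
  X <- as.matrix(X) + state$offset
  if (recipe$do_row_median) X <- median_row_normalize(X)$X
  if (recipe$do_pqn) X <- pqn_normalize(X, reference = state$pqn_reference)$X
  X <- log10(X)
  if (length(state$dropped)) X <- X[, -state$dropped, drop = FALSE]
  if (recipe$do_autoscale) {
    X <- sweep(sweep(X, 2, state$col_means, "-"), 2, state$col_sds, "/")
  }
  X
}
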