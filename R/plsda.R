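# PLS-DA: PLS2 regression on one-hot class indicators, latent-variable
# selection by venetian-blinds cross-validation, repeated double
# cross-validation (rDCV), VIP scores and permutation testing.

.one_hot <- function(y, levels_) {
  Y <- matrix(0, length(y), length(levels_),
              dimnames = list(NULL, levels_))
  Y[cbind(seq_along(y), match(as.character(y), levels_))] <- 1
  Y
}

#' Fit a PLS-DA model
#'
#' Classes are one-hot encoded and column-centered; X is centered (and
#' optionally unit-variance scaled) using constants stored in the model so
#' new samples are projected with the training state only. Each latent
#' variable's X-weight vector is the dominant left singular vector of the
#' current X'Y cross-covariance (the fixed point that NIPALS PLS2 iterates
#' to), followed by the usual t/p/q deflation — fully deterministic for a
#' fixed input.
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels (>= 2 classes, each with >= 1 sample).
#' @param A Number of latent variables, `1 <= A <= min(n-1, p)`.
#' @param scale Autoscale X columns inside the model (default FALSE; enable
#'   when X is not already autoscaled).
#' @return Object of class `plsda_model`: weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, regression coefficients `B`, scores `T`, per-component
#'   explained Y-variance `ssy`, `class_order`, and the centering/scaling
#'   `train_state`.
#' @export
fit_plsda <- function(X, y, A, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  class_order <- sort(unique(y))
  if (length(class_order) < 2L) stop("need at least 2 classes", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (!is.numeric(A) || A < 1) stop("A must be a positive integer", call. = FALSE)
  A <- as.integer(A)
  if (A > min(n - 1, p)) stop("A exceeds min(n-1, p)", call. = FALSE)
  x_means <- colMeans(X)
  x_sds <- if (scale) {
    s <- apply(X, 2, stats::sd); s[s == 0 | !is.finite(s)] <- 1; s
  } else rep(1, p)
  E <- sweep(sweep(X, 2, x_means, "-"), 2, x_sds, "/")
  Y <- .one_hot(y, class_order)
  y_means <- colMeans(Y)
  Fm <- sweep(Y, 2, y_means, "-")
  K <- length(class_order)
  W <- matrix(0, p, A); P <- matrix(0, p, A)
  Q <- matrix(0, K, A); Tm <- matrix(0, n, A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    C <- crossprod(E, Fm)
    sv <- svd(C, nu = 1, nv = 0)
    if (sv$d[1] < 1e-12) {
      stop("no residual X-Y covariance at component ", a, call. = FALSE)
    }
    w <- sv$u[, 1]
    j <- which.max(abs(w)); if (w[j] < 0) w <- -w  # reproducible sign
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt < 1e-12) stop("degenerate score at component ", a, call. = FALSE)
    p_ <- crossprod(E, t_) / tt
    q_ <- crossprod(Fm, t_) / tt
    E <- E - t_ %*% t(p_)
    Fm <- Fm - t_ %*% t(q_)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q_; Tm[, a] <- t_
    ssy[a] <- tt * sum(q_^2)
  }
  R <- W %*% solve(crossprod(P[, seq_len(A), drop = FALSE], W))
  B <- R %*% t(Q)
  dimnames(B) <- list(colnames(X), class_order)
  structure(list(W = W, P = P, Q = Q, B = B, scores = Tm, ssy = ssy,
                 A = A, class_order = class_order,
                 train_state = list(x_means = x_means, x_sds = x_sds,
                                    y_means = y_means, scale = scale)),
            class = "plsda_model")
}

# Coefficients of the truncated model using the first `a` components only.
.plsda_coef <- function(model, a) {
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  Q <- model$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W)) %*% t(Q)
}

#' Predict continuous class responses
#'
#' @param object A `plsda_model`.
#' @param X New samples (same feature count and order as training).
#' @param ncomp Number of latent variables to use (default: all fitted).
#' @param ... Unused.
#' @return Samples-by-classes matrix of predicted one-hot responses.
#' @export
predict.plsda_model <- function(object, X, ncomp = object$A, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$train_state$x_means)) {
    stop("feature count mismatch: model has ",
         length(object$train_state$x_means), ", input has ", ncol(X),
         call. = FALSE)
  }
  st <- object$train_state
  Xc <- sweep(sweep(X, 2, st$x_means, "-"), 2, st$x_sds, "/")
  B <- if (ncomp == object$A) object$B else .plsda_coef(object, ncomp)
  sweep(Xc %*% B, 2, st$y_means, "+")
}

#' Predict class labels
#'
#' Assigns each sample to the class with the largest predicted one-hot
#' response; exact ties break to the first class in `class_order`.
#'
#' @inheritParams predict.plsda_model
#' @param model A `plsda_model`.
#' @return Character vector of class labels (empty for an empty matrix).
#' @export
predict_classes <- function(model, X, ncomp = model$A) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) return(character(0))
  Yhat <- predict(model, X, ncomp = ncomp)
  model$class_order[apply(Yhat, 1, which.max)]
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a ssy_a (w_aj / ||w_a||)^2 / sum_a ssy_a )` where
#' `ssy_a` is the Y-variance explained by component a. By construction the
#' mean of the squared VIPs is 1, so VIP > 1 marks above-average importance.
#'
#' @param model A fitted `plsda_model`.
#' @return Non-negative vector of length p with `mean(vip^2) = 1`.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "plsda_model"))
  if (sum(model$ssy) <= 0) stop("zero explained Y-variance", call. = FALSE)
  p <- nrow(model$W)
  Wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  v <- sqrt(p * as.vector(Wn^2 %*% model$ssy) / sum(model$ssy))
  names(v) <- rownames(model$B)
  v
}

# Venetian-blinds fold assignment: samples ordered by class (stable), then
# fold = position mod folds, so each fold samples every class evenly.
.venetian_folds <- function(y, folds) {
  ord <- order(y)
  fold <- integer(length(y))
  fold[ord] <- ((seq_along(y) - 1L) %% folds) + 1L
  fold
}

#' Select the number of latent variables by cross-validation
#'
#' Venetian-blinds k-fold cross-validation: after class-stratified ordering
#' sample i goes to fold i mod k. The returned A minimizes the mean CV
#' misclassification rate; ties resolve to the smallest A.
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels.
#' @param max_A Largest candidate (capped at min(n_train - 1, p)).
#' @param folds Number of folds (default 5).
#' @param scale Passed to [fit_plsda()].
#' @return List with `A` (chosen), `cv_error` (per-candidate mean
#'   misclassification rate).
#' @export
select_nlv <- function(X, y, max_A, folds = 5, scale = FALSE) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(folds >= 2, max_A >= 1)
  fold <- .venetian_folds(y, folds)
  cap <- min(max_A, ncol(X), nrow(X) - max(table(fold)) - 1L)
  if (cap < 1L) cap <- 1L
  errs <- matrix(NA_real_, folds, cap)
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < length(unique(y))) {
      stop("fold ", f, " training set lacks a class; use fewer folds",
           call. = FALSE)
    }
    a_max <- min(cap, sum(tr) - 1L, ncol(X))
    m <- fit_plsda(X[tr, , drop = FALSE], y[tr], A = a_max, scale = scale)
    for (a in seq_len(a_max)) {
      pred <- predict_classes(m, X[!tr, , drop = FALSE], ncomp = a)
      errs[f, a] <- mean(pred != y[!tr])
    }
  }
  cv <- colMeans(errs, na.rm = TRUE)
  list(A = which.min(cv), cv_error = cv)
}

# Stratified random split into `k` groups; returns integer assignment.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  offset <- 0L
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Classification metrics from a confusion matrix
#'
#' Rows are true classes, columns predicted. Per class c:
#' `sensitivity = TP/(TP+FN) * 100`, `specificity = TN/(TN+FP) * 100`;
#' overall `accuracy = trace/total * 100`. A class with no true samples gets
#' `NA` sensitivity.
#'
#' @param confusion Square non-negative count matrix with matching
#'   dimnames.
#' @return List with `accuracy`, `sensitivity`, `specificity` (named per
#'   class).
#' @export
classification_metrics <- function(confusion) {
  C <- as.matrix(confusion)
  stopifnot(nrow(C) == ncol(C), all(C >= 0))
  total <- sum(C)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(C)
  fn <- rowSums(C) - tp
  fp <- colSums(C) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(rowSums(C) > 0, tp / (tp + fn) * 100, NA_real_)
  spec <- tn / (tn + fp) * 100
  names(sens) <- names(spec) <- rownames(C)
  list(accuracy = sum(tp) / total * 100, sensitivity = sens,
       specificity = spec)
}

#' Repeated double cross-validation of PLS-DA
#'
#' Per repetition the samples are split at random (class-stratified) into
#' `outer` cancellation groups. For every outer fold the inner loop — a
#' venetian-blinds CV with `inner` folds on the outer-training samples only
#' — selects the latent-variable count; a model fit on the outer-training
#' samples (centering/scaling state from those samples only) predicts the
#' held-out group. Accuracy and per-class sensitivity/specificity are
#' aggregated as mean and SD over repetitions; VIP selection frequency is
#' the fraction of all outer models where a feature's VIP exceeds
#' `vip_threshold`.
#'
#' @param X Samples-by-features matrix (typically log10 intensities; each
#'   outer model applies its own training-fold autoscaling when
#'   `scale = TRUE`).
#' @param y Class labels.
#' @param outer,inner Numbers of cancellation groups for the two loops
#'   (default 10 and 10).
#' @param repeats Number of repetitions (default 50).
#' @param max_A Largest candidate latent-variable count.
#' @param seed Integer seed; identical seeds give identical results.
#' @param scale Autoscale within each outer-training fold (default TRUE).
#' @param vip_threshold VIP cutoff for the frequency table (default 1).
#' @return Object of class `rdcv_result`: `accuracy_mean`, `accuracy_sd`,
#'   `sensitivity` / `specificity` (mean and sd matrices, classes as
#'   columns), `misclassification` (row-percent class-by-class matrix),
#'   `vip_frequency`, `chosen_A` (table), `per_repetition` accuracies,
#'   `seed`.
#' @export
rdcv <- function(X, y, outer = 10, inner = 10, repeats = 50, max_A = 10,
                 seed = NULL, scale = TRUE, vip_threshold = 1) {
  X <- as.matrix(X); y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (nrow(X) < outer) stop("fewer samples than outer groups", call. = FALSE)
  if (any(table(y) < outer)) {
    warning("some class has fewer samples than outer groups; ",
            "outer folds will be unbalanced")
  }
  if (!is.null(seed)) set.seed(seed)
  classes <- sort(unique(y))
  K <- length(classes)
  acc <- numeric(repeats)
  sens <- matrix(NA_real_, repeats, K, dimnames = list(NULL, classes))
  spec <- matrix(NA_real_, repeats, K, dimnames = list(NULL, classes))
  mis_sum <- matrix(0, K, K, dimnames = list(classes, classes))
  vip_hits <- numeric(ncol(X)); n_models <- 0L
  chosen <- integer(0)
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(y, outer)
    pred <- character(length(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      sel <- select_nlv(X[tr, , drop = FALSE], y[tr], max_A = max_A,
                        folds = min(inner, sum(tr)), scale = scale)
      m <- fit_plsda(X[tr, , drop = FALSE], y[tr], A = sel$A, scale = scale)
      pred[!tr] <- predict_classes(m, X[!tr, , drop = FALSE])
      vip_hits <- vip_hits + (vip_scores(m) > vip_threshold)
      n_models <- n_models + 1L
      chosen <- c(chosen, sel$A)
    }
    conf <- table(factor(y, classes), factor(pred, classes))
    met <- classification_metrics(conf)
    acc[r] <- met$accuracy
    sens[r, ] <- met$sensitivity
    spec[r, ] <- met$specificity
    mis_sum <- mis_sum + sweep(unclass(conf), 1, rowSums(conf), "/") * 100
  }
  names(vip_hits) <- colnames(X)
  structure(list(
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    sensitivity = list(mean = colMeans(sens), sd = apply(sens, 2, stats::sd)),
    specificity = list(mean = colMeans(spec), sd = apply(spec, 2, stats::sd)),
    misclassification = mis_sum / repeats,
    vip_frequency = vip_hits / n_models,
    chosen_A = table(chosen),
    per_repetition = acc,
    outer = outer, inner = inner, repeats = repeats, seed = seed),
    class = "rdcv_result")
}

#' @export
print.rdcv_result <- function(x, ...) {
  cat(sprintf("rDCV PLS-DA: %d x %d cancellation groups, %d repetitions\n",
              x$outer, x$inner, x$repeats))
  cat(sprintf("  accuracy: %.2f +/- %.2f %%\n", x$accuracy_mean,
              if (is.na(x$accuracy_sd)) 0 else x$accuracy_sd))
  tab <- rbind(sensitivity = x$sensitivity$mean,
               specificity = x$specificity$mean)
  print(round(tab, 2))
  invisible(x)
}

#' Permutation test of PLS-DA classification performance
#'
#' The observed metric is the accuracy of a single-repetition rDCV run. Each
#' of the `B` permutations reruns the identical procedure after randomly
#' reassigning class labels, building the null distribution of accuracies.
#' `p = (#{null >= observed} + 1)/(B + 1)` (add-one correction, never zero).
#'
#' @param X Samples-by-features matrix.
#' @param y Class labels.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param metric Only `"accuracy"` is implemented.
#' @param outer,inner,max_A,scale Passed to [rdcv()].
#' @return Object of class `permutation_result`: `observed`, `null`
#'   (length B), `p_value`, `B`.
#' @export
permutation_test <- function(X, y, B = 1000, seed = NULL,
                             metric = "accuracy", outer = 10, inner = 10,
                             max_A = 10, scale = TRUE) {
  metric <- match.arg(metric, "accuracy")
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, B + 1L)
  obs <- rdcv(X, y, outer = outer, inner = inner, repeats = 1,
              max_A = max_A, seed = sub_seeds[1], scale = scale)$accuracy_mean
  null <- vapply(seq_len(B), function(b) {
    yp <- sample(y)
    rdcv(X, yp, outer = outer, inner = inner, repeats = 1, max_A = max_A,
         seed = sub_seeds[b + 1L], scale = scale)$accuracy_mean
  }, numeric(1))
  structure(list(observed = obs, null = null, B = B,
                 p_value = (sum(null >= obs) + 1) / (B + 1)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test: observed accuracy %.2f%%, B = %d, p = %.4g\n",
              x$observed, x$B, x$p_value))
  invisible(x)
}
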