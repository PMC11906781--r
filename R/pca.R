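# Exploratory PCA: fitting, Hotelling T2 group ellipses, noise-component
# removal with data reconstruction, replicate averaging, and loading
# selection with quadrant/class attribution.

#' Fit a PCA model by singular value decomposition
#'
#' The input is expected to be column-centered (typically autoscaled); no
#' further centering is applied, so scores are exactly `X %*% P`. Explained
#' variance fractions use all singular values of `X`, not just the retained
#' components. Loading signs follow a fixed convention — the largest-|value|
#' element of each loading vector is made positive — so results are
#' reproducible across runs and platforms.
#'
#' @param X Centered/autoscaled samples-by-features matrix.
#' @param A Number of components, `A <= min(n-1, p)` and at most the rank.
#' @return Object of class `pca_model`: `scores` (n x A), `loadings`
#'   (p x A), `explained` (length-A variance fractions), `A`, `sv` (all
#'   singular values).
#' @export
fit_pca <- function(X, A) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(A >= 1)
  if (A > min(n - 1, p)) stop("A exceeds min(n-1, p)", call. = FALSE)
  sv <- svd(X)
  rank_ <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (A > rank_) stop("A exceeds the rank of X (", rank_, ")", call. = FALSE)
  P <- sv$v[, seq_len(A), drop = FALSE]
  # deterministic sign: largest-|element| loading entry positive
  for (a in seq_len(A)) {
    j <- which.max(abs(P[, a]))
    if (P[j, a] < 0) P[, a] <- -P[, a]
  }
  T_ <- X %*% P
  expl <- sv$d[seq_len(A)]^2 / sum(sv$d^2)
  rownames(P) <- colnames(X); rownames(T_) <- rownames(X)
  colnames(P) <- colnames(T_) <- paste0("PC", seq_len(A))
  structure(list(scores = T_, loadings = P, explained = expl, A = A,
                 sv = sv$d),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", nrow(x$scores), "samples,", nrow(x$loadings),
      "features,", x$A, "components\n")
  cat("  explained variance:",
      paste0(sprintf("%.2f%%", 100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Hotelling T-squared confidence ellipse for 2-D scores
#'
#' Computes, for one group of samples, the ellipse enclosing the stated
#' fraction of its score distribution: eigen-decomposition of the 2x2 score
#' covariance with critical value `c = (2(n-1)/(n-2)) * F(conf; 2, n-2)`;
#' the semi-axes are `sqrt(eigenvalue_k * c)` along the eigenvector
#' directions.
#'
#' @param scores2d n x 2 matrix of scores for one group (n >= 4).
#' @param confidence Coverage fraction in (0, 1), default 0.95.
#' @return List: `center` (2-vector), `semi_axes` (2-vector, decreasing),
#'   `angle` (radians, orientation of the major axis), `confidence`, `n`.
#' @export
hotelling_ellipse <- function(scores2d, confidence = 0.95) {
  S2 <- as.matrix(scores2d)
  stopifnot(ncol(S2) == 2, confidence > 0, confidence < 1)
  n <- nrow(S2)
  if (n < 4) stop("need at least 4 samples per group for an ellipse", call. = FALSE)
  ctr <- colMeans(S2)
  V <- stats::cov(S2)
  if (abs(det(V)) < .Machine$double.eps) stop("singular score covariance", call. = FALSE)
  cc <- (2 * (n - 1) / (n - 2)) * stats::qf(confidence, 2, n - 2)
  eg <- eigen(V, symmetric = TRUE)
  list(center = ctr,
       semi_axes = sqrt(pmax(eg$values, 0) * cc),
       angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
       confidence = confidence, n = n)
}

#' Test whether 2-D points fall inside a Hotelling ellipse
#'
#' @param scores2d n x 2 matrix of points.
#' @param ellipse Result of [hotelling_ellipse()].
#' @return Logical vector.
#' @export
in_hotelling_ellipse <- function(scores2d, ellipse) {
  S2 <- sweep(as.matrix(scores2d), 2, ellipse$center, "-")
  R <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  U <- S2 %*% R
  (U[, 1] / ellipse$semi_axes[1])^2 + (U[, 2] / ellipse$semi_axes[2])^2 <= 1
}

#' Remove PCA components and reconstruct the data
#'
#' Subtracts the score-loading outer product of each dropped component:
#' `X_rec = X - sum_d t_d p_d'`. All variance not carried by the dropped
#' components — including residual variance beyond the fitted model — is
#' retained, which is the minimal intervention for excising a systematic
#' artifact (e.g. a batch component) from the data.
#'
#' @param X The matrix the model was fitted on.
#' @param model A `pca_model`.
#' @param drop Integer component indices to remove (subset of `1:A`).
#' @return Reconstructed matrix; the projection of the result onto every
#'   dropped loading is zero to numerical precision.
#' @export
remove_components_and_reconstruct <- function(X, model, drop) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (length(drop) == 0L) return(X)
  drop <- as.integer(drop)
  if (any(drop < 1L | drop > model$A)) {
    stop("drop indices must lie in 1..A (A = ", model$A, ")", call. = FALSE)
  }
  Td <- model$scores[, drop, drop = FALSE]
  Pd <- model$loadings[, drop, drop = FALSE]
  X - Td %*% t(Pd)
}

#' Average technical replicates
#'
#' Collapses rows that share a replicate-group id into their arithmetic
#' mean. When a metadata data.frame is supplied, per-group metadata must be
#' constant for the `class` and `qc` columns (conflicts are an error); the
#' `tech_rep` column is dropped.
#'
#' @param X Samples-by-features matrix.
#' @param groups Replicate-group id per row.
#' @param metadata Optional per-sample data.frame.
#' @return List with `X` (one row per group, in first-appearance order) and
#'   `metadata` (collapsed, or NULL).
#' @export
average_replicates <- function(X, groups, metadata = NULL) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(X))
  ug <- unique(groups)
  M <- rowsum(X, group = factor(groups, levels = ug), reorder = FALSE)
  counts <- as.vector(table(factor(groups, levels = ug)))
  M <- M / counts
  rownames(M) <- ug
  meta_out <- NULL
  if (!is.null(metadata)) {
    stopifnot(nrow(metadata) == nrow(X))
    keep <- setdiff(names(metadata), "tech_rep")
    meta_out <- do.call(rbind, lapply(ug, function(g) {
      rows <- metadata[groups == g, keep, drop = FALSE]
      for (col in intersect(c("class", "qc"), keep)) {
        if (length(unique(rows[[col]])) > 1L) {
          stop("conflicting '", col, "' within replicate group '", g, "'",
               call. = FALSE)
        }
      }
      rows[1, , drop = FALSE]
    }))
    rownames(meta_out) <- NULL
  }
  list(X = M, metadata = meta_out)
}

#' Select influential loadings and attribute quadrants and classes
#'
#' A feature is selected when its absolute loading on PC1 or PC2 reaches
#' `rel_threshold` times the maximum absolute loading of that same
#' component. Each selected feature gets a quadrant from the signs of its
#' two loadings (the four triangle glyphs of a loadings plot) and, when
#' per-class feature means are supplied, the class whose mean has the
#' largest magnitude for that feature.
#'
#' @param model A `pca_model` with at least 2 components.
#' @param rel_threshold Fraction of the per-component maximum |loading| in
#'   (0, 1], default 0.5.
#' @param class_means Optional class-by-feature matrix of (autoscaled) group
#'   means, used for class attribution.
#' @param components Which two components to use (default `c(1, 2)`).
#' @return Data frame: feature, loading1, loading2, quadrant
#'   (`"PC1+/PC2+"` etc.), glyph (one of up/down/right/left triangle names),
#'   and `class` when `class_means` is given.
#' @export
select_loadings <- function(model, rel_threshold = 0.5, class_means = NULL,
                            components = c(1, 2)) {
  stopifnot(inherits(model, "pca_model"), model$A >= 2,
            rel_threshold > 0, rel_threshold <= 1, length(components) == 2)
  P2 <- model$loadings[, components, drop = FALSE]
  if (all(P2 == 0)) {
    return(data.frame(feature = character(0), loading1 = numeric(0),
                      loading2 = numeric(0), quadrant = character(0),
                      glyph = character(0), stringsAsFactors = FALSE))
  }
  thr <- rel_threshold * apply(abs(P2), 2, max)
  sel <- which(abs(P2[, 1]) >= thr[1] | abs(P2[, 2]) >= thr[2])
  quadrant <- paste0("PC1", ifelse(P2[sel, 1] >= 0, "+", "-"),
                     "/PC2", ifelse(P2[sel, 2] >= 0, "+", "-"))
  glyph <- c("PC1+/PC2+" = "up", "PC1-/PC2-" = "down",
             "PC1+/PC2-" = "right", "PC1-/PC2+" = "left")[quadrant]
  out <- data.frame(feature = rownames(P2)[sel] %||% as.character(sel),
                    loading1 = P2[sel, 1], loading2 = P2[sel, 2],
                    quadrant = quadrant, glyph = unname(glyph),
                    stringsAsFactors = FALSE)
  if (!is.null(class_means)) {
    cm <- as.matrix(class_means)[, sel, drop = FALSE]
    out$class <- rownames(cm)[apply(abs(cm), 2, which.max)]
  }
  rownames(out) <- NULL
  out
}

#' Rank components by association with a nuisance covariate
#'
#' Diagnostic helper for choosing which component carries batch or
#' injection-order structure: absolute Pearson correlation of each score
#' vector with the covariate, sorted decreasing. The choice of component to
#' drop remains the caller's.
#'
#' @param model A `pca_model`.
#' @param covariate Numeric per-sample nuisance variable (batch score,
#'   injection order, ...).
#' @return Data frame with `component` and `abs_cor`, sorted decreasing.
#' @export
rank_components_by_covariate <- function(model, covariate) {
  stopifnot(inherits(model, "pca_model"),
            length(covariate) == nrow(model$scores))
  r <- abs(apply(model$scores, 2, stats::cor, y = covariate))
  out <- data.frame(component = seq_len(model$A), abs_cor = r)
  out[order(-out$abs_cor), ]
}
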