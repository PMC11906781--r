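test_that("explained fractions sum to one at full rank and never increase", {
  set.seed(11)
  X <- scale(matrix(rnorm(40), 10, 4), scale = FALSE)
  m <- fit_pca(X, 4)
  expect_equal(sum(m$explained), 1, tolerance = 1e-8)
  expect_true(all(diff(m$explained) <= 1e-12))
})

test_that("loadings are orthonormal and scores orthogonal", {
  for (s in 1:3) {
    set.seed(s)
    X <- scale(matrix(rnorm(15 * 8), 15, 8))
    m <- fit_pca(X, 5)
    expect_equal(crossprod(m$loadings), diag(5), tolerance = 1e-8,
                 ignore_attr = TRUE)
    G <- crossprod(m$scores)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  }
})

test_that("duplicated feature columns receive equal loadings", {
  set.seed(2)
  X <- scale(matrix(rnorm(60), 12, 5))
  Xd <- cbind(X, X[, 3])
  m <- fit_pca(Xd, 3)
  expect_equal(m$loadings[3, ], m$loadings[6, ], tolerance = 1e-8)
})

test_that("a two-feature toy matches the closed-form eigenvalues (1 +/- rho)/2", {
  rho <- 0.99
  # exact construction: columns with unit variance and correlation rho
  set.seed(7)
  Z <- scale(matrix(rnorm(4000), 2000, 2))
  Z <- Z %*% solve(chol(cov(Z)))          # exactly whitened
  X <- Z %*% chol(matrix(c(1, rho, rho, 1), 2))
  m <- fit_pca(scale(X), 2)
  expect_equal(m$explained, c((1 + rho) / 2, (1 - rho) / 2),
               tolerance = 1e-6)
  expect_equal(abs(m$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-6)
})

test_that("component counts beyond min(n-1, p) or the rank are rejected", {
  X <- scale(matrix(rnorm(20), 5, 4))
  expect_error(fit_pca(X, 5), "exceeds")
  Xr1 <- outer(rnorm(6), rnorm(4))          # rank 1, not centered
  expect_error(fit_pca(Xr1, 3), "rank")
})

test_that("loading signs follow the fixed convention across runs", {
  set.seed(9)
  X <- scale(matrix(rnorm(100), 20, 5))
  m1 <- fit_pca(X, 3); m2 <- fit_pca(X, 3)
  expect_identical(m1$loadings, m2$loadings)
  for (a in 1:3) expect_gt(m1$loadings[which.max(abs(m1$loadings[, a])), a], 0)
})

test_that("Hotelling ellipse covers the nominal fraction (Monte Carlo)", {
  set.seed(123)
  S <- matrix(rnorm(2e5), 1e5, 2)
  e <- hotelling_ellipse(S, 0.95)
  cov_frac <- mean(in_hotelling_ellipse(S, e))
  expect_lt(abs(cov_frac - 0.95), 0.005)
})

test_that("Hotelling ellipse geometry behaves in limits and edge cases", {
  set.seed(5)
  S <- matrix(rnorm(400), 200, 2)
  tiny <- hotelling_ellipse(S, 1e-9)
  big <- hotelling_ellipse(S, 0.95)
  expect_true(all(tiny$semi_axes < 1e-3 * big$semi_axes))
  # isotropic covariance: equal semi-axes
  iso <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, 1) / sqrt(2),
               c(-1, -1) / sqrt(2), c(1, -1) / sqrt(2), c(-1, 1) / sqrt(2))
  ei <- hotelling_ellipse(iso, 0.95)
  expect_equal(ei$semi_axes[1], ei$semi_axes[2], tolerance = 1e-8)
  expect_error(hotelling_ellipse(S[1:3, ], 0.95), "at least 4")
  degenerate <- cbind(1:10, 2 * (1:10))
  expect_error(hotelling_ellipse(degenerate, 0.95), "singular")
})

test_that("component removal subtracts exactly the dropped score-loading product", {
  set.seed(14)
  X <- scale(matrix(rnorm(200), 20, 10))
  m <- fit_pca(X, 4)
  expect_identical(remove_components_and_reconstruct(X, m, integer(0)), X)
  Xr <- remove_components_and_reconstruct(X, m, 2)
  # projection onto the dropped loading vanishes
  expect_lt(max(abs(Xr %*% m$loadings[, 2])), 1e-10)
  # Pythagoras: squared norms decompose
  expect_equal(sum(X^2), sum(Xr^2) + sum(m$scores[, 2]^2), tolerance = 1e-8)
  expect_error(remove_components_and_reconstruct(X, m, 9), "1..A")
})

test_that("dropping a component of a rank-2 matrix leaves rank 1", {
  set.seed(15)
  t1 <- rnorm(12); t2 <- rnorm(12)
  X <- outer(t1, rnorm(6)) + outer(t2, rnorm(6))
  X <- scale(X, scale = FALSE)
  m <- fit_pca(X, 2)
  Xr <- remove_components_and_reconstruct(X, m, 2)
  d <- svd(Xr)$d
  expect_gt(d[1], 1e-6)
  expect_lt(d[2] / d[1], 1e-10)
})

test_that("a refit PCA never re-discovers the dropped direction", {
  sim <- generate_dataset(simulation_config(n_features = 40,
                                            n_informative = 8,
                                            effect_size = 1, batch_sd = 1.5,
                                            noise_sd = 0.1, seed = 19))
  au <- autoscale(log10(sim$table$intensities))
  X <- au$X
  v <- sim$truth$batch_loading / au$sds  # batch axis in autoscaled space
  v <- v / sqrt(sum(v^2))
  m <- fit_pca(X, 5)
  cos0 <- abs(as.vector(t(m$loadings) %*% v))
  d <- which.max(cos0)
  Xr <- remove_components_and_reconstruct(X, m, d)
  m2 <- fit_pca(Xr, 5)
  cos_refit <- abs(as.vector(t(m2$loadings) %*% m$loadings[, d]))
  expect_true(all(cos_refit < 0.05))
  cos_batch <- abs(as.vector(t(m2$loadings) %*% v))
  expect_true(all(cos_batch < 0.2))
})

test_that("replicate averaging takes arithmetic means and guards metadata", {
  X <- rbind(c(1, 1), c(1, 1), c(1, 3), c(3, 3))
  g <- c("a", "a", "b", "b")
  out <- average_replicates(X, g)
  expect_equal(unname(out$X["a", ]), c(1, 1))
  expect_equal(unname(out$X["b", ]), c(2, 3))

  meta <- data.frame(sample_id = 1:4, class = c("X", "X", "Y", "Z"),
                     bio_rep = g, tech_rep = c(1, 2, 1, 2),
                     qc = FALSE, injection_order = 1:4)
  expect_error(average_replicates(X, g, meta), "conflicting")
})

test_that("averaging commutes with reconstruction when replicates share scores", {
  set.seed(23)
  # exact duplicate technical replicates: scores are shared within groups
  base <- matrix(rnorm(5 * 8), 5, 8)
  X <- scale(base[rep(1:5, each = 3), ], scale = FALSE)
  g <- rep(letters[1:5], each = 3)
  m <- fit_pca(X, 2)
  rec_then_avg <- average_replicates(
    remove_components_and_reconstruct(X, m, 2), g)$X
  avg <- average_replicates(X, g)$X
  t_avg <- average_replicates(m$scores[, 2, drop = FALSE], g)$X
  avg_then_rec <- avg - t_avg %*% t(m$loadings[, 2, drop = FALSE])
  expect_equal(rec_then_avg, avg_then_rec, tolerance = 1e-10)
})

test_that("loading selection thresholds per component and assigns quadrants", {
  P <- cbind(c(1.0, 0.6, 0.4, -0.00325, 0.2),
             c(0.1, 0.05, 0.9, 0.00044, -0.85))
  rownames(P) <- paste0("F", 1:5)
  model <- structure(list(loadings = P, A = 2,
                          scores = matrix(0, 1, 2), explained = c(0.5, 0.3)),
                     class = "pca_model")
  sel <- select_loadings(model, 0.5)
  expect_setequal(sel$feature, c("F1", "F2", "F3", "F5"))
  expect_equal(sel$quadrant[sel$feature == "F5"], "PC1+/PC2-")
  expect_equal(sel$glyph[sel$feature == "F5"], "right")

  # a small PC1-negative / PC2-positive loading lands in the left quadrant
  sel_all <- select_loadings(model, 1e-6)
  expect_equal(sel_all$quadrant[sel_all$feature == "F4"], "PC1-/PC2+")
  expect_equal(sel_all$glyph[sel_all$feature == "F4"], "left")
})

test_that("loading selection attributes the class with the largest mean magnitude", {
  P <- cbind(c(0.9, -0.8), c(0.1, 0.7))
  rownames(P) <- c("F1", "F2")
  model <- structure(list(loadings = P, A = 2), class = "pca_model")
  cm <- rbind(CTRL = c(0.1, -2), H2O2 = c(1.5, 0.3))
  sel <- select_loadings(model, 0.5, class_means = cm)
  expect_equal(sel$class[sel$feature == "F1"], "H2O2")
  expect_equal(sel$class[sel$feature == "F2"], "CTRL")
})

test_that("components correlated with a nuisance covariate rank first", {
  set.seed(31)
  X <- scale(matrix(rnorm(300), 30, 10))
  m <- fit_pca(X, 3)
  covariate <- m$scores[, 2] + rnorm(30, sd = 0.1)
  r <- rank_components_by_covariate(m, covariate)
  expect_equal(r$component[1], 2)
})
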