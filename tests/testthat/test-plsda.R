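test_that("a separable two-class problem is fit perfectly with one LV", {
  d <- separable_2class()
  m <- fit_plsda(d$X, d$y, A = 1)
  expect_equal(predict_classes(m, d$X), d$y)
})

test_that("duplicating every feature leaves predictions unchanged", {
  d <- separable_2class(seed = 7)
  m1 <- fit_plsda(d$X, d$y, A = 2)
  m2 <- fit_plsda(cbind(d$X, d$X), d$y, A = 2)
  expect_equal(predict_classes(m1, d$X),
               predict_classes(m2, cbind(d$X, d$X)))
})

test_that("degenerate fits are rejected", {
  d <- separable_2class()
  expect_error(fit_plsda(d$X, d$y, A = 0), "positive")
  expect_error(fit_plsda(d$X, rep("A", nrow(d$X)), A = 1), "2 classes")
  expect_error(fit_plsda(d$X, d$y, A = 50), "exceeds")
})

test_that("prediction handles ties, empty input and dimension mismatches", {
  d <- separable_2class()
  m <- fit_plsda(d$X, d$y, A = 1)
  expect_identical(predict_classes(m, d$X[0, , drop = FALSE]), character(0))
  expect_error(predict_classes(m, d$X[, 1:2]), "mismatch")
  # a sample at the training centroid scores the centered class priors for
  # every class: an exact tie, resolved to the first class in class_order
  centroid <- matrix(colMeans(d$X), 1)
  expect_equal(predict_classes(m, centroid), "A")
})

test_that("VIP scores satisfy the normalization identity", {
  expect_equal(unname(vip_scores(fit_plsda(
    matrix(c(1, 2, 3, 10, 11, 12), 6, 1), rep(c("A", "B"), each = 3), 1))), 1)
  for (s in 1:3) {
    d <- separable_4class(n_per = 5, p = 12, seed = s)
    m <- fit_plsda(d$X, d$y, A = 3)
    v <- vip_scores(m)
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), ncol(d$X), tolerance = 1e-8)
  }
})

test_that("VIP reproduces the direct formula for a known weight vector", {
  # planted single-component structure with weight direction (0.8, 0.6)
  t_ <- c(1, 1, -1, -1, 2, -2)
  X <- outer(t_, c(0.8, 0.6))
  y <- ifelse(t_ > 0, "A", "B")
  m <- fit_plsda(X, y, A = 1)
  expect_equal(unname(m$W[, 1]), c(0.8, 0.6), tolerance = 1e-8)
  expect_equal(unname(vip_scores(m)), sqrt(2) * c(0.8, 0.6),
               tolerance = 1e-8)
})

test_that("latent-variable selection recovers planted one-component structure", {
  set.seed(12)
  t_ <- rep(c(-1, 1), each = 10) + rnorm(20, sd = 0.05)
  X <- outer(t_, rnorm(8)) + matrix(rnorm(160, sd = 0.01), 20, 8)
  y <- rep(c("A", "B"), each = 10)
  sel <- select_nlv(X, y, max_A = 4, folds = 5)
  expect_equal(sel$A, 1L)
  expect_equal(select_nlv(X, y, max_A = 1)$A, 1L)
})

test_that("venetian-blinds folds are class-balanced", {
  y <- rep(c("A", "B", "C"), each = 6)
  fold <- chemomet:::.venetian_folds(y, 3)
  for (f in 1:3) expect_equal(as.integer(table(y[fold == f])), rep(2L, 3))
})

test_that("classification metrics match direct counting", {
  # rows true, cols predicted: A -> 8 correct, 2 as B; B -> 1 as A, 9 correct
  C <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("A", "B")))
  met <- classification_metrics(C)
  expect_equal(met$accuracy, 85)
  expect_equal(unname(met$sensitivity), c(80, 90))
  expect_equal(unname(met$specificity), c(90, 80))

  D <- diag(c(5, 3, 7)); dimnames(D) <- list(letters[1:3], letters[1:3])
  md <- classification_metrics(D)
  expect_true(all(md$sensitivity == 100) && all(md$specificity == 100))
  expect_error(classification_metrics(matrix(0, 2, 2)), "empty")
})

test_that("rDCV is seed-deterministic and accurate on separable classes", {
  d <- separable_4class(n_per = 8, p = 16, gap = 5, noise = 0.5)
  r1 <- suppressWarnings(rdcv(d$X, d$y, outer = 8, inner = 4, repeats = 3,
                              max_A = 4, seed = 101))
  r2 <- suppressWarnings(rdcv(d$X, d$y, outer = 8, inner = 4, repeats = 3,
                              max_A = 4, seed = 101))
  expect_identical(r1$per_repetition, r2$per_repetition)
  expect_identical(r1$vip_frequency, r2$vip_frequency)
  expect_gte(r1$accuracy_mean, 95)
  expect_true(all(r1$vip_frequency >= 0 & r1$vip_frequency <= 1))
  # misclassification rows are percentages summing to 100
  expect_equal(unname(rowSums(r1$misclassification)), rep(100, 4),
               tolerance = 0.1)
})

test_that("rDCV accuracy sits at chance for label-independent data", {
  set.seed(55)
  X <- matrix(rnorm(80 * 15), 80, 15)
  y <- rep(c("CTRL", "M", "H2O2", "M+H2O2"), each = 20)
  r <- suppressWarnings(rdcv(X, y, outer = 10, inner = 5, repeats = 5,
                             max_A = 3, seed = 77))
  expect_lt(abs(r$accuracy_mean - 25), 7)
})

test_that("rDCV accuracy grows with planted effect size", {
  accs <- vapply(c(0.3, 1, 3), function(g) {
    d <- separable_4class(n_per = 6, p = 12, gap = g, noise = 1, seed = 5)
    suppressWarnings(rdcv(d$X, d$y, outer = 6, inner = 4, repeats = 2,
                          max_A = 3, seed = 9))$accuracy_mean
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("permutation test hits the p-value floor on separable data", {
  d <- separable_4class(n_per = 5, p = 10, gap = 6, noise = 0.4)
  pt <- suppressWarnings(permutation_test(d$X, d$y, B = 19, seed = 3,
                                          outer = 5, inner = 4, max_A = 3))
  expect_equal(pt$observed, 100)
  expect_equal(pt$p_value, 1 / 20)
  expect_error(permutation_test(d$X, d$y, B = 0), "B must be")
})

test_that("the model state comes from training samples only", {
  d <- separable_2class(n_per = 8)
  train <- c(1:6, 9:14); test <- setdiff(1:16, train)
  m <- fit_plsda(d$X[train, ], d$y[train], A = 2, scale = TRUE)
  expect_equal(m$train_state$x_means, colMeans(d$X[train, ]))
  # perturbing held-out samples cannot change the fitted model
  m2 <- fit_plsda(d$X[train, ], d$y[train], A = 2, scale = TRUE)
  expect_identical(m$B, m2$B)
  shifted <- d$X[test, ] + 5
  expect_equal(predict(m, shifted),
               predict(m2, d$X[test, ] + 5))
})
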