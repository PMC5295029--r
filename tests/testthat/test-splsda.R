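test_that("dense (keepX = p) component 1 matches the PLS singular direction", {
  for (i in 1:10) {
    X <- toy_matrix(10, 6, seed = i)
    y <- toy_labels(10)
    fit <- fit_splsda(X, y, ncomp = 1, keepX = 6)
    Xs <- scale(X)
    Y <- scale(stats::model.matrix(~ y - 1), scale = FALSE)
    u <- svd(crossprod(Xs, Y))$u[, 1]
    cosang <- abs(sum(fit$x_weights[, 1] * u)) /
      sqrt(sum(fit$x_weights[, 1]^2) * sum(u^2))
    expect_gt(cosang, 0.9999)
  }
})

test_that("successive scores are orthogonal (regression deflation)", {
  X <- toy_matrix(20, 8, seed = 3)
  fit <- fit_splsda(X, toy_labels(20), ncomp = 3, keepX = c(8, 4, 2))
  G <- crossprod(fit$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  # each weight vector: exactly keepX non-zeros, unit norm
  expect_identical(colSums(fit$x_weights != 0), c(8, 4, 2))
  expect_equal(unname(sqrt(colSums(fit$x_weights^2))), rep(1, 3))
})

test_that("explained variance: rank-1 data gives 1; additive; matches residual oracle", {
  # rank-1 X whose single direction separates classes
  set.seed(4)
  t1 <- c(rnorm(5, -2), rnorm(5, 2))
  load <- rnorm(3)
  X <- outer(t1, load)
  dimnames(X) <- list(sprintf("s%d", 1:10), sprintf("f%d", 1:3))
  X <- X + matrix(rnorm(30, sd = 1e-8), 10, 3)   # break exact ties only
  fit1 <- fit_splsda(X, toy_labels(10), ncomp = 1, keepX = 3)
  expect_equal(fit1$explained_variance_x[1], 1.0, tolerance = 1e-6)

  # 5 x 3 toy: fractions equal projection residual-norm differences
  X2 <- toy_matrix(5, 3, seed = 9)
  fit2 <- fit_splsda(X2, toy_labels(5, 2), ncomp = 2, keepX = 3)
  Xs <- scale(X2)
  res <- Xs
  oracle <- numeric(2)
  for (h in 1:2) {
    t_h <- fit2$x_scores[, h]
    proj <- t_h %*% t(crossprod(res, t_h) / sum(t_h^2))
    oracle[h] <- sum(proj^2) / sum(Xs^2)
    res <- res - proj
  }
  expect_equal(fit2$explained_variance_x, oracle, tolerance = 1e-10)
  ev <- explained_variance(fit2)
  expect_equal(ev$cumulative, cumsum(ev$per_component))
})

test_that("keepX = 1 on a single-informative-feature toy selects the planted one", {
  set.seed(5)
  X <- toy_matrix(6, 4, seed = 5)
  y <- toy_labels(6)
  X[y == "b", 2] <- X[y == "b", 2] + 5
  # exhaustive oracle: feature maximizing |cor(scaled feature, dummy)|
  Xs <- scale(X)
  Y1 <- scale(stats::model.matrix(~ y - 1), scale = FALSE)[, 1]
  oracle <- colnames(X)[which.max(abs(drop(crossprod(Xs, Y1))))]
  expect_identical(oracle, "f02")
  fit <- fit_splsda(X, y, ncomp = 1, keepX = 1)
  expect_identical(selected_features(fit, 1), oracle)
})

test_that("selection agrees with the reference sparse PLS-DA implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  X <- toy_matrix(30, 20, seed = 11)
  y <- toy_labels(30)
  X[y == "b", 3] <- X[y == "b", 3] + 2
  X[y == "b", 7] <- X[y == "b", 7] + 1.5
  ours <- fit_splsda(X, y, ncomp = 2, keepX = c(5, 5))
  ref <- mixOmics::splsda(X, y, ncomp = 2, keepX = c(5, 5))
  for (h in 1:2) {
    w <- ours$x_weights[, h]; v <- ref$loadings$X[, h]
    expect_setequal(names(w)[w != 0], rownames(ref$loadings$X)[v != 0])
  }
  w1 <- ours$x_weights[, 1]; v1 <- ref$loadings$X[, 1]
  expect_gt(abs(sum(w1 * v1)) / sqrt(sum(w1^2) * sum(v1^2)), 0.9)
})

test_that("max-distance prediction: argmax, separable training data, tie rule", {
  set.seed(6)
  X <- toy_matrix(12, 3, seed = 6)
  y <- toy_labels(12)
  X[y == "b", 1] <- X[y == "b", 1] + 10
  fit <- fit_splsda(X, y, ncomp = 1, keepX = 3)
  pr <- predict_splsda(fit, X)
  expect_equal(as.character(pr$class), as.character(y))
  expect_identical(colnames(pr$scores), levels(y))
  # argmax of the dummy row decides; exact tie -> first class in class_map
  row <- pr$scores[1, ]
  expect_identical(as.character(pr$class[1]),
                   names(row)[which.max(row)])
  fake <- fit
  fake$coefficients[] <- 0
  fake$y_center <- c(0.5, 0.5)
  tie <- predict_splsda(fake, X)
  expect_true(all(tie$class == fit$class_map[1]))
  # missing feature is reported
  expect_error(predict_splsda(fit, X[, 1:2]), "f03")
})

test_that("fit validates inputs (constant feature, too many components)", {
  X <- toy_matrix(8, 3, seed = 7)
  X[, 2] <- 5
  expect_error(fit_splsda(X, toy_labels(8), 1, 3), "f02")
  expect_error(fit_splsda(toy_matrix(4, 10), toy_labels(4), ncomp = 5),
               "exceeds")
  expect_error(fit_splsda(toy_matrix(8, 3), toy_labels(8), 1, keepX = 9),
               "keepX")
})

test_that("tuning is deterministic and finds a small keepX on a dominant feature", {
  set.seed(8)
  X <- toy_matrix(40, 30, seed = 8)
  y <- factor(rep(c("a", "b"), c(14, 26)))
  X[y == "b", 5] <- X[y == "b", 5] + 4   # one dominant discriminator
  tun1 <- tune_splsda(X, y, max_ncomp = 2, keepX_grid = c(1, 2, 3, 5, 10),
                      folds = 5, seed = 9)
  tun2 <- tune_splsda(X, y, max_ncomp = 2, keepX_grid = c(1, 2, 3, 5, 10),
                      folds = 5, seed = 9)
  expect_identical(tun1, tun2)
  expect_lte(tun1$keepX_path[1], 3)
  expect_lt(min(tun1$best_error), 0.15)
})

test_that("component 1 recovers planted miRNAs when keepX equals the planted count", {
  rec <- vapply(1:5, function(s) {
    co <- small_cohort(seed = s)
    fit <- fit_splsda(co$mirna, co$labels, ncomp = 1,
                      keepX = length(co$truth$component1_mirnas))
    mean(co$truth$component1_mirnas %in% selected_features(fit, 1))
  }, numeric(1))
  expect_gte(mean(rec), 0.9)
})
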