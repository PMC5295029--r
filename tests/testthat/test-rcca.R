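test_that("unregularized fit matches the classical CCA oracle", {
  set.seed(1)
  for (i in 1:20) {
    X <- toy_matrix(20, 5, seed = i, prefix = "x")
    Z <- toy_matrix(20, 4, seed = 100 + i, prefix = "z")
    fit <- fit_rcca(X, Z, 0, 0)
    oracle <- stats::cancor(scale(X), scale(Z))$cor
    expect_lt(max(abs(fit$canonical_correlations[1:4] - oracle)), 1e-8)
  }
})

test_that("identical single columns give correlation 1; degenerate lambda errors", {
  set.seed(2)
  v <- stats::rnorm(10)
  X <- matrix(v, 10, 1, dimnames = list(sprintf("s%d", 1:10), "x1"))
  Z <- matrix(v, 10, 1, dimnames = list(sprintf("s%d", 1:10), "z1"))
  fit <- fit_rcca(X, Z, 0, 0)
  expect_equal(fit$canonical_correlations[1], 1, tolerance = 1e-10)
  # singular covariance at lambda = 0 (p > n) is refused with advice
  Xw <- toy_matrix(5, 8, seed = 3)
  Zw <- toy_matrix(5, 2, seed = 4, prefix = "z")
  expect_error(fit_rcca(Xw, Zw, 0, 0), "lambda > 0")
  expect_silent(fit_rcca(Xw, Zw, 0.1, 0.1))
})

test_that("regularized toy maximum matches a grid-search oracle over weight angles", {
  X <- toy_matrix(3, 2, seed = 5, prefix = "x")
  Z <- toy_matrix(3, 2, seed = 6, prefix = "z")
  lam <- 0.1
  fit <- fit_rcca(X, Z, lam, lam)
  Xs <- scale(X); Zs <- scale(Z)
  Sxx <- crossprod(Xs) / 2 + diag(lam, 2)
  Szz <- crossprod(Zs) / 2 + diag(lam, 2)
  Sxz <- crossprod(Xs, Zs) / 2
  th <- seq(0, pi, length.out = 2000)
  B <- rbind(cos(th), sin(th))
  qb <- colSums(B * (Szz %*% B))
  best <- 0
  for (t1 in th) {
    a <- c(cos(t1), sin(t1))
    qa <- drop(t(a) %*% Sxx %*% a)
    rho <- abs(drop(t(a) %*% Sxz %*% B)) / sqrt(qa * qb)
    best <- max(best, rho)
  }
  # the model's first regularized criterion value, recomputed from weights
  a <- fit$x_weights[, 1]; b <- fit$z_weights[, 1]
  rho_fit <- abs(drop(t(a) %*% Sxz %*% b)) /
    sqrt(drop(t(a) %*% Sxx %*% a) * drop(t(b) %*% Szz %*% b))
  expect_lt(abs(rho_fit - best), 1e-3)
  expect_gte(best + 1e-3, rho_fit)
})

test_that("canonical correlations are invariant to feature permutation", {
  X <- toy_matrix(15, 6, seed = 7, prefix = "x")
  Z <- toy_matrix(15, 5, seed = 8, prefix = "z")
  f1 <- fit_rcca(X, Z, 0.05, 0.05)
  f2 <- fit_rcca(X[, sample(6)], Z[, sample(5)], 0.05, 0.05)
  expect_equal(f1$canonical_correlations, f2$canonical_correlations,
               tolerance = 1e-10)
})

test_that("large penalties shrink weights toward the cross-covariance singular direction", {
  set.seed(9)
  X <- toy_matrix(20, 5, seed = 9, prefix = "x")
  Z <- toy_matrix(20, 4, seed = 10, prefix = "z")
  Sxz <- crossprod(scale(X), scale(Z)) / 19
  u <- svd(Sxz)$u[, 1]
  align <- vapply(c(0.1, 1, 10, 100, 1000), function(l) {
    a <- fit_rcca(X, Z, l, l)$x_weights[, 1]
    abs(sum(a * u)) / sqrt(sum(a^2))
  }, numeric(1))
  expect_true(all(diff(align) > -1e-8))
  expect_gt(align[length(align)], 0.999)
})

test_that("null blocks give small first correlations that shrink with n", {
  set.seed(10)
  rho_n <- vapply(c(30, 120), function(n) {
    mean(vapply(1:5, function(i) {
      X <- toy_matrix(n, 3, seed = n + i, prefix = "x")
      Z <- toy_matrix(n, 3, seed = 1000 + n + i, prefix = "z")
      fit_rcca(X, Z, 0, 0)$canonical_correlations[1]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(rho_n[2], rho_n[1])
  expect_lt(rho_n[2], 0.5)
})

test_that("penalty tuning is deterministic and recovers a shared signal", {
  set.seed(11)
  n <- 30
  s <- stats::rnorm(n)
  X <- sapply(1:4, function(i) s + stats::rnorm(n, sd = 0.5))
  Z <- sapply(1:3, function(i) s + stats::rnorm(n, sd = 0.5))
  dimnames(X) <- list(sprintf("s%d", 1:n), sprintf("x%d", 1:4))
  dimnames(Z) <- list(sprintf("s%d", 1:n), sprintf("z%d", 1:3))
  g1 <- c(0.01, 0.1, 1); g2 <- c(0.01, 0.1, 1)
  t1 <- tune_rcca(X, Z, g1, g2, folds = 5, seed = 12)
  t2 <- tune_rcca(X, Z, g1, g2, folds = 5, seed = 12)
  expect_identical(t1, t2)
  expect_gt(max(t1$cv_score), 0.6)
  expect_error(tune_rcca(X, Z, g1, g2, folds = 15, seed = 1), "fewer folds")
})

test_that("dimension selection by the largest-gap rule", {
  expect_equal(select_dimensions(c(0.9, 0.85, 0.2, 0.1)), 2L)
  expect_equal(select_dimensions(c(0.9, 0.1)), 1L)
  expect_warning(d <- select_dimensions(c(0.5, 0.5, 0.5)), "no clear gap")
  expect_equal(d, 1L)
  expect_warning(d2 <- select_dimensions(seq(0.9, 0.1, length.out = 5)),
                 "no clear gap")
  expect_equal(d2, 1L)
  expect_message(d3 <- select_dimensions(c(0.9, 0.2, 0.1), override = 3),
                 "override")
  expect_equal(d3, 3L)
  expect_error(select_dimensions(0.9), "at least 2")
})

test_that("correlation circle retains associated features and drops noise", {
  set.seed(13)
  n <- 60
  s1 <- stats::rnorm(n); s2 <- stats::rnorm(n)
  X <- cbind(x1 = s1 + stats::rnorm(n, sd = 0.2),
             x2 = s2 + stats::rnorm(n, sd = 0.2),
             x3 = stats::rnorm(n))
  Z <- cbind(z1 = -s1 + stats::rnorm(n, sd = 0.2),
             z2 = -s2 + stats::rnorm(n, sd = 0.2))
  Znoise <- matrix(stats::rnorm(n * 60), n,
                   dimnames = list(NULL, sprintf("zn%02d", 1:60)))
  rownames(X) <- sprintf("s%d", 1:n)
  Zall <- cbind(Z, Znoise); rownames(Zall) <- rownames(X)
  fit <- fit_rcca(X, Zall, 0.1, 0.1, ncomp = 2)
  pts <- correlation_circle(fit, X, Zall, inner_radius = 0.3)
  expect_true(all(c("x1", "x2", "z1", "z2") %in% pts$feature_id))
  # pure-noise genes are rarely retained at radius 0.3
  expect_lt(mean(sprintf("zn%02d", 1:60) %in% pts$feature_id), 0.35)
  expect_true(all(abs(pts$dim1) <= 1 + 1e-12))
  expect_true(all(pts$radius <= sqrt(2)))
  expect_error(correlation_circle(fit, X, Zall, inner_radius = 1.2), "0, 1")
})

test_that("CIM similarity is the coordinate inner product with average-linkage orders", {
  pts <- data.frame(
    feature_id = c("m1", "m2", "g1", "g2", "g3"),
    block = c("mirna", "mirna", "gene", "gene", "gene"),
    dim1 = c(1, -1, 1, -1, 0.5),
    dim2 = c(0, 0, 0, 0, 0.5))
  pts$radius <- sqrt(pts$dim1^2 + pts$dim2^2)
  cim <- cim_similarity(pts)
  expect_equal(cim$similarity["m1", "g1"], 1)
  expect_equal(cim$similarity["m1", "g2"], -1)
  expect_equal(cim$similarity["m2", "g3"], -0.5)
  # oracle inner products for the whole matrix
  Mi <- as.matrix(pts[pts$block == "mirna", c("dim1", "dim2")])
  Ge <- as.matrix(pts[pts$block == "gene", c("dim1", "dim2")])
  expect_equal(unname(cim$similarity), unname(Mi %*% t(Ge)))
  # average-linkage merge heights, computed by hand for the 3 gene points:
  # d(g1,g2) = 2, d(g1,g3) = sqrt(0.5), d(g2,g3) = sqrt(2.5);
  # first merge (g1,g3) at sqrt(0.5), then g2 joins at mean(2, sqrt(2.5))
  expect_equal(cim$col_hclust$height,
               c(sqrt(0.5), mean(c(2, sqrt(2.5)))))
  expect_error(cim_similarity(pts[pts$block == "gene", ]), "per block")
})
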