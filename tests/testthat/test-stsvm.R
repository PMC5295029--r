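test_that("normalized Laplacian: single edge, triangle spectrum, isolated nodes", {
  g1 <- build_feature_graph(data.frame(mirna = "a", gene = "b"))
  expect_equal(unname(g1$laplacian), matrix(c(1, -1, -1, 1), 2))
  tri <- build_feature_graph(data.frame(mirna = c("a", "a", "b"),
                                        gene = c("b", "c", "c")))
  expect_equal(sort(eigen(tri$laplacian)$values), c(0, 1.5, 1.5),
               tolerance = 1e-10)
  iso <- build_feature_graph(data.frame(mirna = "a", gene = "b"),
                             nodes = c("a", "b", "lonely"))
  expect_equal(iso$laplacian["lonely", ], c(a = 0, b = 0, lonely = 0))
  expect_true(isSymmetric(iso$adjacency))
  expect_equal(unname(diag(iso$adjacency)), rep(0, 3))
})

test_that("random-walk kernel: identity at 0 steps, one-edge case, PSD, a-bound", {
  g <- build_feature_graph(data.frame(mirna = "a", gene = "b"))
  expect_equal(unname(random_walk_kernel(g, 2, 0)), diag(2))
  expect_equal(unname(random_walk_kernel(g, 2, 1)), matrix(1, 2, 2))
  expect_error(random_walk_kernel(g, 1.5, 1), "PSD|psd|not PSD|indefinite")
  expect_error(random_walk_kernel(g, 2, 1.5), "integer")
  set.seed(1)
  for (i in 1:10) {
    nn <- sample(4:10, 1)
    edges <- data.frame(mirna = sprintf("m%d", sample(nn, 12, TRUE)),
                        gene = sprintf("g%d", sample(nn, 12, TRUE)))
    edges <- edges[!duplicated(edges), ]
    gr <- build_feature_graph(edges)
    ev <- eigen(gr$laplacian, symmetric = TRUE)$values
    expect_true(all(ev > -1e-10 & ev < 2 + 1e-10))
    K <- random_walk_kernel(gr, 2, sample(1:3, 1))
    expect_true(isSymmetric(K, tol = 1e-10))
    expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("kernel smoothing: identity, one-edge equalization, isolated invariance", {
  g <- build_feature_graph(data.frame(mirna = "a", gene = "b"),
                           nodes = c("a", "b", "iso"))
  raw <- c(a = 3, b = 1, iso = 2)
  K0 <- random_walk_kernel(g, 2, 0)
  s0 <- smooth_statistics(K0, raw)
  expect_equal(unname(s0), unname(raw / max(raw)))
  K1 <- random_walk_kernel(g, 2, 1)
  s1 <- smooth_statistics(K1, raw)
  expect_equal(s1[["a"]], s1[["b"]])     # connected pair equalized: both 4
  expect_equal(s1[["iso"]], 2 * 2 / 4)   # isolated: a * raw, up to rescale
  expect_error(smooth_statistics(K1, raw[1:2]), "dimension")
  expect_error(smooth_statistics(K1, c(b = 1, a = 3, iso = 2)), "order")
})

test_that("permutation selection finds planted features; steps = 0 equals plain t-selection", {
  co <- small_cohort(seed = 3)
  planted <- c(co$truth$signature_mirnas, co$truth$signature_genes)
  edges <- co$truth$target_map
  net_edges <- data.frame(mirna = edges$mirna, gene = edges$gene)
  g <- build_feature_graph(net_edges)
  comb <- cbind(co$mirna$values[, intersect(g$nodes, feature_ids(co$mirna))],
                co$gene$values[, intersect(g$nodes, feature_ids(co$gene))])
  comb <- comb[, g$nodes]
  K <- random_walk_kernel(g, 2, 2)
  sel <- permutation_select(comb, co$labels$label, K, n_perm = 200, seed = 4)
  expect_true(all(planted %in% sel$selected))
  sel_b <- permutation_select(comb, co$labels$label, K, n_perm = 200, seed = 4)
  expect_identical(sel_b, sel)

  # steps = 0: identical to unsmoothed |t| permutation selection
  K0 <- random_walk_kernel(g, 2, 0)
  sel0 <- permutation_select(comb, co$labels$label, K0, n_perm = 200,
                             seed = 4)
  t_obs <- abs(random_variance_ttest(comb, co$labels$label)$t)
  set.seed(4)
  exceed <- integer(ncol(comb))
  for (b in 1:200) {
    tp <- abs(random_variance_ttest(comb,
                                    sample(co$labels$label))$t)
    exceed <- exceed + (tp >= t_obs)
  }
  p_plain <- (1 + exceed) / 201
  expect_equal(unname(sel0$p), p_plain)
})

test_that("selection is calibrated when labels carry no signal", {
  set.seed(5)
  X <- toy_matrix(40, 30, seed = 5)
  edges <- data.frame(mirna = sprintf("f%02d", 1:10),
                      gene = sprintf("f%02d", 21:30))
  g <- build_feature_graph(edges, nodes = colnames(X))
  K <- random_walk_kernel(g, 2, 2)
  y <- factor(rep(c("a", "b"), 20))
  hits <- 0; trials <- 0
  for (i in 1:5) {
    sel <- tryCatch(
      permutation_select(X, sample(y), K, n_perm = 150, alpha = 0.05,
                         seed = i)$selected,
      error = function(e) character(0))
    hits <- hits + length(sel); trials <- trials + ncol(X)
  }
  expect_lt(hits / trials, 0.15)
})

test_that("rank AUC equals the pair-counting oracle and CV behaves at the extremes", {
  set.seed(6)
  for (i in 1:30) {
    n <- sample(6:20, 1)
    sc <- stats::rnorm(n)
    sc[sample(n, 2)] <- sc[1]   # include ties
    pos <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[1] <- FALSE
    brute <- mean(outer(sc[pos], sc[!pos],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc_rank(sc, pos), brute, tolerance = 1e-12)
  }
  expect_error(auc_rank(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  # perfectly separated classes -> AUC 1
  set.seed(7)
  X <- rbind(matrix(stats::rnorm(10 * 3, 0), 10, 3),
             matrix(stats::rnorm(10 * 3, 8), 10, 3))
  dimnames(X) <- list(sprintf("s%d", 1:20), sprintf("f%d", 1:3))
  y <- factor(rep(c("a", "b"), each = 10))
  cv <- cv_evaluate(X, y, repeats = 3, folds = 5, seed = 8)
  expect_equal(cv$auc_mean, 1.0)
  expect_equal(length(cv$auc_per_repeat), 3)
  expect_true(all(cv$roc$fpr >= 0 & cv$roc$tpr <= 1))

  # label-independent features -> AUC near 1/2
  null_auc <- vapply(1:5, function(s) {
    Xn <- toy_matrix(30, 4, seed = 50 + s)
    cv_evaluate(Xn, toy_labels(30), repeats = 2, folds = 5,
                seed = s)$auc_mean
  }, numeric(1))
  expect_gt(mean(null_auc), 0.3)
  expect_lt(mean(null_auc), 0.7)
})

test_that("full stSVM stage recovers the planted signature on a synthetic cohort", {
  co <- small_cohort(seed = 9)
  keep <- variance_top_fraction(co$gene, 0.75)
  ac <- pairwise_anticorrelation(
    co$mirna$values[, co$truth$component1_mirnas, drop = FALSE],
    co$gene$values[, intersect(colnames(co$gene$values)[1:60], keep),
                   drop = FALSE])
  net <- build_integrated_network(ac, consensus_predictions(co$db_edges, 2),
                                  0.1)
  sig <- run_stsvm(co$mirna, co$gene, co$labels, net, n_perm = 200,
                   repeats = 3, folds = 5, seed = 10)
  planted <- c(co$truth$signature_mirnas, co$truth$signature_genes)
  expect_gte(mean(planted %in% sig$selected), 0.8)
  expect_gt(sig$cv$auc_mean, 0.9)
  # a size-matched random background signature performs worse
  set.seed(11)
  rand_feats <- sample(setdiff(feature_ids(co$gene),
                               c(co$truth$signature_genes,
                                 unlist(co$truth$pathway_genes))),
                       length(sig$selected))
  cv_rand <- cv_evaluate(co$gene$values[, rand_feats], co$labels$label,
                         repeats = 3, folds = 5, seed = 12)
  expect_lt(cv_rand$auc_mean, sig$cv$auc_mean)
})
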