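test_that("variance top-fraction ranking, ceiling and tie rule", {
  Z <- cbind(g1 = c(1, 2, 3, 10), g2 = c(1, 1, 1, 1.1),
             g3 = c(5, -5, 5, -5), g4 = c(0, 1, 0, 1))
  rownames(Z) <- sprintf("s%d", 1:4)
  expect_setequal(variance_top_fraction(Z, 1), colnames(Z))
  top3 <- variance_top_fraction(Z, 0.75)   # ceiling(3) by direct variances
  ord <- order(-apply(Z, 2, var), colnames(Z))
  expect_identical(top3, colnames(Z)[ord][1:3])
  # tie at the cut: lower feature id wins
  Zt <- cbind(b = c(0, 1, 0, 1), a = c(1, 0, 1, 0), c = c(9, 0, 0, 0))
  rownames(Zt) <- sprintf("s%d", 1:4)
  expect_identical(variance_top_fraction(Zt, 0.5), c("c", "a"))
  expect_error(variance_top_fraction(Z, 0), "fraction")
})

test_that("pairwise anticorrelation: exact case, Pearson oracle, constant skip", {
  set.seed(1)
  n <- 6
  X <- toy_matrix(n, 2, seed = 1, prefix = "m")
  Z <- cbind(g1 = -X[, 1], g2 = stats::rnorm(n))
  rownames(Z) <- rownames(X)
  tab <- pairwise_anticorrelation(X, Z)
  row <- tab[tab$mirna == "m01" & tab$gene == "g1", ]
  expect_equal(row$r, -1, tolerance = 1e-12)
  expect_lt(row$p, 1e-10)
  # closed-form oracle on every pair
  for (i in seq_len(nrow(tab))) {
    x <- X[, tab$mirna[i]]; y <- Z[, tab$gene[i]]
    r_or <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(tab$r[i] - r_or), 1e-12)
  }
  # q = BH over all tested pairs
  expect_equal(tab$q, bh_fdr(tab$p))
  Zc <- cbind(Z, g3 = rep(2, n))
  expect_message(tab2 <- pairwise_anticorrelation(X, Zc), "g3")
  expect_false("g3" %in% tab2$gene)
  expect_error(pairwise_anticorrelation(X[1:3, ], Z[1:3, ]), "4 samples")
})

test_that("database consensus counts support and honors min_support", {
  d1 <- target_prediction_set("d1", c("m1", "m1", "m2"), c("g1", "g2", "g1"))
  d2 <- target_prediction_set("d2", c("m1", "m3"), c("g1", "g9"))
  d3 <- target_prediction_set("d3", c("m1", "m2"), c("g2", "g1"))
  cons2 <- consensus_predictions(list(d1, d2, d3), 2)
  expect_equal(nrow(cons2), 3)
  expect_equal(cons2$db_support[cons2$mirna == "m1" & cons2$gene == "g1"], 2)
  expect_false("g9" %in% cons2$gene)   # single-database edge dropped
  cons1 <- consensus_predictions(list(d1, d2, d3), 1)   # plain union
  expect_equal(nrow(cons1), 4)
  cons3 <- consensus_predictions(list(d1, d2, d3), 3)
  expect_equal(nrow(cons3), 0)
  expect_warning(
    consensus_predictions(list(d1, target_prediction_set("e", character(0),
                                                         character(0))), 1),
    "empty")
  expect_error(consensus_predictions(list(d1), 5), "min_support")
})

test_that("integrated network is exactly the intersection of its two filters", {
  anticorr <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m3"),
    gene = c("g1", "g2", "g1", "g3", "g4"),
    r = c(-0.9, -0.8, -0.7, 0.5, -0.6),
    p = c(1e-5, 1e-4, 1e-3, 0.9, 0.01),
    q = c(1e-4, 1e-3, 0.05, 0.95, 0.2))
  consensus <- data.frame(mirna = c("m1", "m1", "m2", "m2", "m3"),
                          gene = c("g1", "g2", "g1", "g3", "g4"),
                          db_support = c(3, 2, 2, 2, 2))
  # 3 edges pass both filters; m2-g3 fails r < 0, m3-g4 fails q < 0.1
  net <- build_integrated_network(anticorr, consensus, max_q = 0.1)
  expect_equal(nrow(net$edges), 3)
  expect_setequal(net$mirnas, c("m1", "m2"))
  expect_true(all(net$edges$r < 0))
  expect_warning(empty <- build_integrated_network(anticorr, consensus, 0),
                 "empty")
  expect_equal(nrow(empty$edges), 0)

  # brute force over random subsets of candidate edges
  set.seed(2)
  for (i in 1:20) {
    k <- sample(5:20, 1)
    ac <- data.frame(mirna = sprintf("m%d", sample(5, k, TRUE)),
                     gene = sprintf("g%d", sample(6, k, TRUE)),
                     r = stats::runif(k, -1, 1),
                     p = stats::runif(k), q = stats::runif(k))
    ac <- ac[!duplicated(paste(ac$mirna, ac$gene)), ]
    keep_cons <- sample(c(TRUE, FALSE), nrow(ac), TRUE)
    cons <- data.frame(mirna = ac$mirna[keep_cons],
                       gene = ac$gene[keep_cons],
                       db_support = 2)
    net_i <- suppressWarnings(build_integrated_network(ac, cons, 0.5))
    manual <- ac[ac$q < 0.5 & ac$r < 0 & keep_cons, c("mirna", "gene")]
    expect_setequal(edge_key(net_i$edges$mirna, net_i$edges$gene),
                    edge_key(manual$mirna, manual$gene))
  }
})

test_that("hub statistics: star coverage, disjoint stars, tie rule", {
  star <- build_integrated_network(
    data.frame(mirna = "m1", gene = sprintf("g%d", 1:5),
               r = -0.9, p = 1e-5, q = 1e-4),
    data.frame(mirna = "m1", gene = sprintf("g%d", 1:5), db_support = 2),
    max_q = 0.1)
  hs <- hub_statistics(star, top_k = 1)
  expect_equal(hs$coverage, 1.0)

  two <- build_integrated_network(
    data.frame(mirna = rep(c("mA", "mB"), each = 3),
               gene = sprintf("g%d", 1:6), r = -0.9, p = 1e-5, q = 1e-4),
    data.frame(mirna = rep(c("mA", "mB"), each = 3),
               gene = sprintf("g%d", 1:6), db_support = 2),
    max_q = 0.1)
  hs2 <- hub_statistics(two, top_k = 1)
  expect_equal(hs2$coverage, 0.5)            # 3 of 6 edges
  expect_identical(hs2$top_mirnas, "mA")     # degree tie -> lower node id
  hs3 <- hub_statistics(two, top_k = 2, min_cotarget = 1)
  expect_equal(hs3$coverage, 1.0)
  expect_length(hs3$cotargeted_genes, 6)
  expect_error(hub_statistics(build_integrated_network(
    data.frame(mirna = character(0), gene = character(0), r = numeric(0),
               p = numeric(0), q = numeric(0)),
    data.frame(mirna = character(0), gene = character(0),
               db_support = integer(0)), 0.1) |> suppressWarnings()),
    "empty")
})

test_that("planted edges are recovered with high F1 on synthetic cohorts", {
  f1s <- vapply(1:5, function(s) {
    co <- generate_cohort(seed = s)
    keep <- variance_top_fraction(co$gene, 0.75)
    ac <- pairwise_anticorrelation(
      co$mirna$values[, co$truth$component1_mirnas, drop = FALSE],
      co$gene$values[, intersect(colnames(co$gene$values)[1:100], keep),
                     drop = FALSE])
    net <- build_integrated_network(ac, consensus_predictions(co$db_edges, 2),
                                    0.1)
    f1_score(edge_key(net$edges$mirna, net$edges$gene),
             edge_key(co$truth$target_map$mirna, co$truth$target_map$gene))
  }, numeric(1))
  expect_gte(mean(f1s), 0.8)
})
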