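# Shared small fixtures, built once per test run.

# compact cohort for module-level tests (fast to generate)
small_cohort <- function(seed = 42, ...) {
  generate_cohort(n_class0 = 8, n_class1 = 12, p_mirna = 100,
                  q_gene = 300, n_pathway_gene = 20, n_null_sets = 3,
                  seed = seed, ...)
}

# tiny deterministic expression matrix
toy_matrix <- function(n = 6, p = 4, seed = 1, prefix = "f") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("%s%02d", prefix, seq_len(p))))
  m
}

toy_labels <- function(n = 6, n0 = n %/% 2) {
  factor(rep(c("a", "b"), c(n0, n - n0)))
}

edge_key <- function(mirna, gene) paste(mirna, gene, sep = "\r")

f1_score <- function(predicted_key, true_key) {
  tp <- sum(predicted_key %in% true_key)
  if (tp == 0) return(0)
  prec <- tp / length(predicted_key)
  rec <- tp / length(true_key)
  2 * prec * rec / (prec + rec)
}
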