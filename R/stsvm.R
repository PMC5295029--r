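#' Feature graph of an integrated network
#'
#' Converts the bipartite miRNA-gene network into an undirected,
#' unweighted graph over the union of its nodes and computes the
#' symmetric normalized Laplacian `L = I - D^(-1/2) A D^(-1/2)`. Isolated
#' nodes (possible when `nodes` widens the set) get a zero Laplacian row,
#' so kernel smoothing leaves them untouched.
#'
#' @param net `IntegratedNetwork` (non-empty) or a data frame of
#'   `mirna`/`gene` edges.
#' @param nodes optional node set to build over (defaults to the
#'   network's own nodes).
#' @return `FeatureGraph`: list with `nodes`, `adjacency`, `laplacian`.
#' @export
build_feature_graph <- function(net, nodes = NULL) {
  edges <- if (inherits(net, "IntegratedNetwork")) net$edges else net
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$mirna, edges$gene)))
  }
  if (!length(nodes)) stop("no nodes")
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    i <- match(edges$mirna, nodes); j <- match(edges$gene, nodes)
    ok <- !is.na(i) & !is.na(j)
    A[cbind(i[ok], j[ok])] <- 1
    A[cbind(j[ok], i[ok])] <- 1
  }
  diag(A) <- 0
  d <- rowSums(A)
  dm <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(ifelse(d > 0, 1, 0), nrow = length(nodes)) - (dm %o% dm) * A
  dimnames(L) <- dimnames(A)
  structure(list(nodes = nodes, adjacency = A, laplacian = L),
            class = "FeatureGraph")
}

#' p-step random-walk kernel
#'
#' `K = (a I - L)^steps` with `L` the symmetric normalized Laplacian.
#' Because the Laplacian spectrum lies in [0, 2], `a >= 2` guarantees a
#' positive semidefinite kernel; smaller values are rejected. `steps = 0`
#' gives the identity (no smoothing).
#'
#' @param graph `FeatureGraph`.
#' @param a kernel offset, >= 2.
#' @param steps non-negative integer number of walk steps (default 2).
#' @return symmetric kernel matrix over the graph nodes.
#' @export
random_walk_kernel <- function(graph, a = 2, steps = 2) {
  if (a < 2) {
    stop("`a` must be >= 2: normalized-Laplacian eigenvalues reach 2, so ",
         "smaller offsets make (aI - L) indefinite and the kernel not PSD")
  }
  if (steps < 0 || steps != round(steps)) {
    stop("`steps` must be a non-negative integer")
  }
  L <- graph$laplacian
  K <- diag(nrow(L)); dimnames(K) <- dimnames(L)
  if (steps == 0) return(K)
  B <- a * diag(nrow(L)) - L
  for (i in seq_len(steps)) K <- K %*% B
  dimnames(K) <- dimnames(L)
  K
}

#' Smooth per-node statistics over the kernel
#'
#' `s = K |t|`, rescaled to unit maximum so smoothed scores are
#' comparable across permutations regardless of the kernel's overall
#' scale.
#'
#' @param kernel kernel matrix from [random_walk_kernel()].
#' @param raw named numeric vector of per-node raw scores (typically
#'   |t|), in kernel node order.
#' @return named numeric vector of smoothed scores, max = 1.
#' @export
smooth_statistics <- function(kernel, raw) {
  if (length(raw) != nrow(kernel)) {
    stop("score length does not match kernel dimension")
  }
  if (!is.null(names(raw)) && !is.null(rownames(kernel)) &&
      !identical(names(raw), rownames(kernel))) {
    stop("score names do not match kernel node order")
  }
  s <- drop(kernel %*% raw)
  names(s) <- rownames(kernel)
  mx <- max(s)
  if (mx > 0) s <- s / mx
  s
}

#' Permutation selection of network-smoothed features
#'
#' Observed per-feature scores are the kernel-smoothed absolute
#' random-variance t-statistics of the combined miRNA+gene matrix; the
#' null is built by permuting class labels and recomputing the smoothed
#' scores. Per-feature p-values use the add-one convention; features with
#' p < `alpha` are selected.
#'
#' @param x_combined samples x nodes matrix (or [expression_matrix()])
#'   with columns in kernel node order.
#' @param y labels as in [random_variance_ttest()].
#' @param kernel kernel matrix over the same nodes.
#' @param n_perm number of label permutations (>= 100).
#' @param alpha selection threshold (default 0.05).
#' @param seed integer seed.
#' @return list with `selected` (ids), `p` (per-feature), `score`
#'   (observed smoothed scores).
#' @export
permutation_select <- function(x_combined, y, kernel, n_perm = 1000,
                               alpha = 0.05, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  X <- get_values(x_combined)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x_combined, y) else
    factor(y)
  if (!identical(colnames(X), rownames(kernel))) {
    stop("columns of `x_combined` must match kernel node order")
  }
  # the permutation null compares raw (unrescaled) smoothed scores:
  # rescaling each permutation to unit maximum would cancel the overall
  # signal strength the test is meant to detect
  obs_raw <- drop(kernel %*% abs(random_variance_ttest(X, lab)$t))
  obs <- smooth_statistics(kernel, abs(random_variance_ttest(X, lab)$t))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  exceed <- integer(length(obs_raw))
  for (b in seq_len(n_perm)) {
    sp <- drop(kernel %*% abs(random_variance_ttest(X, sample(lab))$t))
    exceed <- exceed + (sp >= obs_raw)
  }
  p <- (1 + exceed) / (n_perm + 1)
  names(p) <- colnames(X)
  selected <- names(p)[p < alpha]
  if (!length(selected)) {
    stop("no feature selected at alpha = ", alpha,
         "; consider a larger alpha")
  }
  list(selected = selected, p = p, score = obs)
}

#' Repeated stratified cross-validated SVM evaluation
#'
#' Trains a linear support vector machine (fixed cost 1, class weights
#' inversely proportional to class size to offset the cohort imbalance)
#' on each training fold, pools the held-out decision values within each
#' repeat, and computes the AUC by the rank (Mann-Whitney) statistic with
#' class1 (the second label level) as the positive class. Feature
#' selection is NOT redone inside the folds by default, mirroring the
#' evaluation wiring this pipeline reproduces; pass the preselected
#' matrix from an outer selection, or use `nested_selection` in
#' [run_stsvm()] for honest estimates.
#'
#' @param x samples x selected-features matrix (or
#'   [expression_matrix()]).
#' @param y labels.
#' @param repeats,folds CV design (default 10 x 10).
#' @param seed integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return list with `auc_mean`, `auc_sd`, `auc_per_repeat`, and `roc`
#'   (pooled FPR/TPR points over all repeats).
#' @export
cv_evaluate <- function(x, y, repeats = 10, folds = 10, seed = 1,
                        cost = 1) {
  X <- get_values(x)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else factor(y)
  if (repeats < 1 || folds < 2) stop("need repeats >= 1 and folds >= 2")
  pos <- levels(lab)[2]
  cw <- stats::setNames(as.numeric(length(lab) / (2 * table(lab))),
                        levels(lab))
  aucs <- numeric(repeats)
  all_dv <- numeric(0); all_lab <- factor(character(0), levels = levels(lab))
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(lab, folds, seed = seed * 100 + r)
    dv <- numeric(length(lab))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (!any(!tr)) next
      if (nlevels(droplevels(lab[tr])) < 2) {
        stop("a training fold contains a single class")
      }
      fit <- e1071::svm(X[tr, , drop = FALSE], lab[tr], kernel = "linear",
                        cost = cost, scale = FALSE,
                        class.weights = cw)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE],
                           decision.values = TRUE)
      d <- drop(attr(pr, "decision.values"))
      # orient decision values so larger => positive class
      lev <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
      if (lev[1] == pos) dv[!tr] <- d else dv[!tr] <- -d
    }
    aucs[r] <- auc_rank(dv, lab == pos)
    all_dv <- c(all_dv, dv); all_lab <- c(all_lab, lab)
  }
  list(auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
       auc_per_repeat = aucs,
       roc = roc_points(all_dv, all_lab == pos))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney rank sum
#' (ties counted one half), equivalent to the pair-counting probability
#' that a positive scores above a negative.
#'
#' @param score numeric decision values.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute an AUC")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC curve points (FPR, TPR) at every distinct threshold
roc_points <- function(score, positive) {
  ord <- order(-score)
  tp <- cumsum(positive[ord]); fp <- cumsum(!positive[ord])
  keep <- !duplicated(score[ord], fromLast = TRUE)
  data.frame(fpr = c(0, fp[keep] / max(sum(!positive), 1)),
             tpr = c(0, tp[keep] / max(sum(positive), 1)))
}

#' Run the full stSVM stage
#'
#' Builds the feature graph from the integrated network, smooths the
#' combined matrix's absolute moderated t-statistics with the
#' `steps`-step random-walk kernel, selects features by label
#' permutation, and evaluates the selected signature by repeated
#' stratified cross-validated linear SVM.
#'
#' @param x,z miRNA and gene blocks (samples x features).
#' @param y labels.
#' @param net `IntegratedNetwork` providing the node set and adjacency.
#' @param a,steps kernel parameters (defaults 2 and 2).
#' @param n_perm,alpha permutation-selection parameters.
#' @param repeats,folds CV design.
#' @param seed integer seed.
#' @param nodes optional node set overriding the network's (e.g. all
#'   rCCA-retained features; isolated nodes then smooth to themselves).
#' @param nested_selection redo permutation selection inside every CV
#'   training fold (honest but slower) instead of once on the full data.
#' @return `SignatureModel`-like list: `selected`, `p`, `score`, `cv`
#'   (from [cv_evaluate()]), `graph`, `kernel`.
#' @export
run_stsvm <- function(x, z, y, net, a = 2, steps = 2, n_perm = 1000,
                      alpha = 0.05, repeats = 10, folds = 10, seed = 1,
                      nodes = NULL, nested_selection = FALSE) {
  X <- get_values(x); Z <- get_values(z)
  graph <- build_feature_graph(net, nodes = nodes)
  avail <- c(colnames(X), colnames(Z))
  missing <- setdiff(graph$nodes, avail)
  if (length(missing)) {
    stop("network node(s) absent from the expression blocks: ",
         paste(missing, collapse = ", "))
  }
  comb <- cbind(X[, intersect(graph$nodes, colnames(X)), drop = FALSE],
                Z[, intersect(graph$nodes, colnames(Z)), drop = FALSE])
  comb <- comb[, graph$nodes, drop = FALSE]
  kernel <- random_walk_kernel(graph, a = a, steps = steps)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else factor(y)
  sel <- permutation_select(comb, lab, kernel, n_perm = n_perm,
                            alpha = alpha, seed = seed)
  cv <- if (nested_selection) {
    cv_evaluate_nested(comb, lab, kernel, n_perm, alpha, repeats, folds,
                       seed)
  } else {
    cv_evaluate(comb[, sel$selected, drop = FALSE], lab,
                repeats = repeats, folds = folds, seed = seed)
  }
  structure(list(selected = sel$selected, p = sel$p, score = sel$score,
                 cv = cv, graph = graph, kernel = kernel,
                 nested_selection = nested_selection),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d selected feature(s), CV AUC %.3f +/- %.3f\n",
              length(x$selected), x$cv$auc_mean, x$cv$auc_sd))
  invisible(x)
}

# nested variant: redo the permutation selection on every training fold
cv_evaluate_nested <- function(comb, lab, kernel, n_perm, alpha, repeats,
                               folds, seed) {
  pos <- levels(lab)[2]
  cw <- stats::setNames(as.numeric(length(lab) / (2 * table(lab))),
                        levels(lab))
  aucs <- numeric(repeats)
  all_dv <- numeric(0); all_pos <- logical(0)
  for (r in seq_len(repeats)) {
    fold_id <- stratified_folds(lab, folds, seed = seed * 100 + r)
    dv <- numeric(length(lab))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (!any(!tr)) next
      sel_f <- tryCatch(
        permutation_select(comb[tr, , drop = FALSE], lab[tr], kernel,
                           n_perm = n_perm, alpha = alpha,
                           seed = seed + f)$selected,
        error = function(e) colnames(comb))
      fit <- e1071::svm(comb[tr, sel_f, drop = FALSE], lab[tr],
                        kernel = "linear", cost = 1, scale = FALSE,
                        class.weights = cw)
      pr <- stats::predict(fit, comb[!tr, sel_f, drop = FALSE],
                           decision.values = TRUE)
      d <- drop(attr(pr, "decision.values"))
      lev <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
      dv[!tr] <- if (lev[1] == pos) d else -d
    }
    aucs[r] <- auc_rank(dv, lab == pos)
    all_dv <- c(all_dv, dv); all_pos <- c(all_pos, lab == pos)
  }
  list(auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
       auc_per_repeat = aucs, roc = roc_points(all_dv, all_pos))
}
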