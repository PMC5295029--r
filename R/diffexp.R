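#' Random-variance moderated two-sample t-test
#'
#' Two-sample t-tests in which each feature's pooled variance is shrunk
#' toward an inverse-gamma prior fitted across all features, so features
#' are not assumed to share one variance yet single-feature variance
#' estimates are stabilized. With prior shape `a` and the prior target
#' variance written `1/b`, the moderated variance and test are
#' \deqn{\tilde s^2 = ((n-2) s^2 + 2a/b) / (n - 2 + 2a),\quad
#'       t = \Delta\bar x / (\tilde s \sqrt{1/n_1 + 1/n_2}),\quad
#'       df = n - 2 + 2a.}
#'
#' The prior is fitted by method of moments on the log pooled variances:
#' under the model `log s^2 = log sigma^2 + log(chi^2_nu / nu)` with
#' `1/sigma^2 ~ Gamma(a, rate a/b)`, so
#' `Var(log s^2) = trigamma(a) + trigamma(nu/2)` and
#' `E(log s^2) = log(a/b) - digamma(a) + digamma(nu/2) + log 2 - log nu`.
#' `a` is recovered by inverting the trigamma function on the excess
#' log-variance spread and `b` follows from the mean equation. When the
#' observed spread is no larger than the pure chi-square component the
#' moments are inconsistent and the fit falls back to `a = 0`, the
#' ordinary pooled t-test.
#'
#' @param x [expression_matrix()] or samples x features matrix.
#' @param y [class_labels()] or two-level factor. Fold changes are
#'   reported as class0 minus class1 (positive = higher in the first
#'   level).
#' @param prior optional list(a, b) to override the fitted prior (a = 0
#'   reproduces the ordinary pooled t-test exactly).
#' @return `DiffExpTable` data frame: per-feature class means, log2 fold
#'   change (`log2_fc`), raw and shrunken variance, `t`, `df`, two-sided
#'   `p`, and BH `q`; the fitted prior is attached as attribute `prior`.
#' @export
random_variance_ttest <- function(x, y, prior = NULL) {
  X <- get_values(x)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else factor(y)
  if (nlevels(lab) != 2) stop("y must have exactly two classes")
  n1 <- sum(lab == levels(lab)[1]); n2 <- sum(lab == levels(lab)[2])
  if (n1 < 2 || n2 < 2) stop("each class needs >= 2 samples")
  n <- n1 + n2; nu <- n - 2

  X1 <- X[lab == levels(lab)[1], , drop = FALSE]
  X2 <- X[lab == levels(lab)[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ss1 <- colSums(sweep(X1, 2, m1)^2)
  ss2 <- colSums(sweep(X2, 2, m2)^2)
  s2 <- (ss1 + ss2) / nu

  if (is.null(prior)) prior <- fit_variance_prior(s2, nu)
  a <- prior$a; b <- prior$b
  if (a > 0) {
    s2_mod <- (nu * s2 + 2 * a / b) / (nu + 2 * a)
    df <- nu + 2 * a
  } else {
    s2_mod <- s2
    df <- nu
  }
  tstat <- (m1 - m2) / sqrt(s2_mod * (1 / n1 + 1 / n2))
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  out <- data.frame(feature_id = colnames(X),
                    mean_class0 = m1, mean_class1 = m2,
                    log2_fc = m1 - m2,
                    s2 = s2, s2_shrunk = s2_mod,
                    t = tstat, df = df, p = pval,
                    q = bh_fdr(pval),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- prior
  class(out) <- c("DiffExpTable", "data.frame")
  out
}

# Method-of-moments fit of the inverse-gamma variance prior on log s^2.
# Solves psigamma(a, 1) = var(log s2) - psigamma(nu/2, 1) for a (trigamma
# inversion by uniroot on a bracketing interval), then b from the mean.
fit_variance_prior <- function(s2, nu) {
  ls <- log(s2[s2 > 0])
  if (length(ls) < 3 || stats::var(ls) < 1e-12) {
    warning("across-feature variances are (nearly) identical; ",
            "falling back to the ordinary t-test")
    return(list(a = 0, b = NA_real_))
  }
  excess <- stats::var(ls) - psigamma(nu / 2, 1)
  if (excess <= 0) {
    return(list(a = 0, b = NA_real_))
  }
  # trigamma is monotone decreasing on (0, Inf): bracket then invert
  f <- function(a) psigamma(a, 1) - excess
  lo <- 1e-4; hi <- 1e6
  if (f(lo) < 0) return(list(a = 0, b = NA_real_))  # spread too large to fit
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  # E[log s2] = log(b/a) ... with 1/sigma^2 ~ Gamma(a, rate a/b):
  # E[log sigma^2] = log(a/b) - digamma(a); E[log chi2_nu/nu] =
  # digamma(nu/2) + log 2 - log nu
  m <- mean(ls)
  log_a_over_b <- m + digamma(a) - digamma(nu / 2) - log(2) + log(nu)
  b <- a / exp(log_a_over_b)
  list(a = a, b = b)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' q(i) = min over j >= i (in p-value rank order) of p(j) * m / j, capped
#' at 1 and returned in the original order. Input values outside [0, 1]
#' are rejected.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed features by q-value and fold change
#'
#' Retains features with `q <= max_q` and `|log2_fc| > min_abs_log2fc`
#' (strict inequality on the fold change, so a fold change of exactly 1
#' log2 unit is excluded), and reports how many selected features are up
#' in each class.
#'
#' @param table `DiffExpTable` from [random_variance_ttest()].
#' @param min_abs_log2fc fold-change threshold (default 1).
#' @param max_q FDR threshold (default 0.15).
#' @return list with `features` (id vector), `direction` (factor
#'   `up_class0`/`up_class1` per selected feature), `n_up_class0`,
#'   `n_up_class1`, and the selected `table` rows.
#' @export
fold_change_filter <- function(table, min_abs_log2fc = 1, max_q = 0.15) {
  keep <- table$q <= max_q & abs(table$log2_fc) > min_abs_log2fc
  sel <- table[keep, , drop = FALSE]
  dir <- factor(ifelse(sel$log2_fc > 0, "up_class0", "up_class1"),
                levels = c("up_class0", "up_class1"))
  list(features = sel$feature_id, direction = dir,
       n_up_class0 = sum(dir == "up_class0"),
       n_up_class1 = sum(dir == "up_class1"),
       table = sel)
}

#' Global class-difference permutation test
#'
#' Permutes the class labels, recomputes every feature's random-variance
#' t-test and the BH correction, and reports the proportion of
#' permutations yielding at least as many features significant at
#' `fdr_threshold` as the true labels do (with the add-one convention, so
#' the smallest achievable p is 1/(n_perm + 1)).
#'
#' @param x,y data and labels as in [random_variance_ttest()].
#' @param n_perm number of permutations (>= 100).
#' @param fdr_threshold FDR significance threshold (default 0.15).
#' @param seed integer seed.
#' @return list with `p_value`, `observed_significant`, and the permuted
#'   counts.
#' @export
global_permutation_test <- function(x, y, n_perm = 1000,
                                    fdr_threshold = 0.15, seed = 1) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  X <- get_values(x)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else factor(y)
  obs <- sum(random_variance_ttest(X, lab)$q <= fdr_threshold)
  if (obs == 0) {
    warning("no feature significant at the chosen FDR; p-value set to 1")
    return(list(p_value = 1, observed_significant = 0L,
                perm_counts = integer(0)))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  counts <- vapply(seq_len(n_perm), function(i) {
    sum(random_variance_ttest(X, sample(lab))$q <= fdr_threshold)
  }, integer(1))
  list(p_value = (1 + sum(counts >= obs)) / (n_perm + 1),
       observed_significant = obs,
       perm_counts = counts)
}
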