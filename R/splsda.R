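#' Sparse PLS discriminant analysis
#'
#' Fits a sparse partial least squares discriminant model: the class factor
#' is coded as a centered dummy matrix (one column per class) and latent
#' components are extracted by an iterated power step on the deflated
#' cross-covariance, with the x-weight vector hard-truncated to its
#' `keepX[h]` largest-magnitude entries and renormalized at every
#' iteration. Features are centered and scaled to unit variance
#' internally; X is deflated by regression on each component's score
#' (regression-mode deflation, so successive scores are orthogonal).
#'
#' Ties at the truncation boundary are broken by feature index order, and
#' each weight vector's sign is fixed so its largest-magnitude entry is
#' positive, making fits deterministic.
#'
#' @param x [expression_matrix()] or samples x features matrix.
#' @param y [class_labels()] (or factor of length n with two levels).
#' @param ncomp number of components H; must be <= min(n - 1, p).
#' @param keepX integer vector (recycled to length `ncomp`) of non-zero
#'   loadings per component, each in 1..p.
#' @param tol,max_iter convergence tolerance and iteration cap of the
#'   inner power loop.
#' @return `SplsdaModel`: weights (`x_weights` p x H), scores
#'   (`x_scores` n x H), x/y loadings, `keepX`, per-component
#'   `explained_variance_x` (fractions of the centered-scaled X variance),
#'   centering/scaling parameters, regression coefficients for prediction,
#'   and `class_map` (level order of the dummy columns).
#' @export
fit_splsda <- function(x, y, ncomp = 2, keepX = NULL,
                       tol = 1e-6, max_iter = 500) {
  X0 <- get_values(x)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else
    factor(y)
  if (nlevels(lab) != 2) stop("y must have exactly two classes")
  n <- nrow(X0); p <- ncol(X0)
  if (ncomp < 1) stop("`ncomp` must be >= 1")
  if (ncomp > min(n - 1, p)) {
    stop(sprintf("`ncomp` = %d exceeds min(n - 1, p) = %d",
                 ncomp, min(n - 1, p)))
  }
  if (is.null(keepX)) keepX <- rep(p, ncomp)
  keepX <- rep_len(as.integer(keepX), ncomp)
  if (any(keepX < 1 | keepX > p)) stop("`keepX` entries must lie in 1..p")

  x_center <- colMeans(X0)
  x_scale <- apply(X0, 2, stats::sd)
  zero_var <- which(x_scale == 0)
  if (length(zero_var)) {
    stop("constant (zero-variance) feature(s): ",
         paste(colnames(X0)[zero_var], collapse = ", "))
  }
  Xs <- scale(X0, center = x_center, scale = x_scale)

  Y0 <- stats::model.matrix(~ lab - 1)
  colnames(Y0) <- levels(lab)
  y_center <- colMeans(Y0)
  Ys <- scale(Y0, center = y_center, scale = FALSE)

  W <- matrix(0, p, ncomp, dimnames = list(colnames(X0), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X0), NULL))
  P <- matrix(0, p, ncomp, dimnames = list(colnames(X0), NULL))
  C <- matrix(0, 2, ncomp, dimnames = list(levels(lab), NULL))
  Xh <- Xs; Yh <- Ys
  total_var <- sum(Xs^2)
  ev <- numeric(ncomp)

  for (h in seq_len(ncomp)) {
    M <- crossprod(Xh, Yh)                       # p x K
    b <- svd(M, nu = 0, nv = 1)$v[, 1]
    a <- rep(0, p)
    for (it in seq_len(max_iter)) {
      a_raw <- drop(M %*% b)
      a_new <- truncate_keep(a_raw, keepX[h])
      nrm <- sqrt(sum(a_new^2))
      if (nrm == 0) stop("degenerate weight vector in component ", h)
      a_new <- a_new / nrm
      b_new <- drop(crossprod(M, a_new))
      b_new <- b_new / sqrt(sum(b_new^2))
      if (max(abs(a_new - a)) < tol) { a <- a_new; b <- b_new; break }
      a <- a_new; b <- b_new
    }
    # deterministic sign: largest-|a| entry positive
    s <- sign(a[which.max(abs(a))]); if (s < 0) { a <- -a; b <- -b }
    t_h <- drop(Xh %*% a)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xh, t_h)) / tt
    c_h <- drop(crossprod(Yh, t_h)) / tt
    W[, h] <- a; Tm[, h] <- t_h; P[, h] <- p_h; C[, h] <- c_h
    ev[h] <- tt * sum(p_h^2) / total_var
    Xh <- Xh - tcrossprod(t_h, p_h)
    Yh <- Yh - tcrossprod(t_h, c_h)
  }

  # PLS regression coefficients on the centered-scaled scale
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(C)

  structure(list(ncomp = ncomp, keepX = keepX,
                 x_weights = W, x_scores = Tm, x_loadings = P,
                 y_loadings = C, coefficients = B,
                 explained_variance_x = ev,
                 cum_explained_variance_x = cumsum(ev),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, class_map = levels(lab)),
            class = "SplsdaModel")
}

# keep the k largest-|v| entries, ties by index order, zero the rest
truncate_keep <- function(v, k) {
  if (k >= length(v)) return(v)
  ord <- order(-abs(v), seq_along(v))
  out <- numeric(length(v))
  out[ord[seq_len(k)]] <- v[ord[seq_len(k)]]
  out
}

#' @export
print.SplsdaModel <- function(x, ...) {
  cat(sprintf("SplsdaModel: %d component(s), keepX = %s, expl. var = %s\n",
              x$ncomp, paste(x$keepX, collapse = "/"),
              paste(sprintf("%.2f", x$explained_variance_x), collapse = "/")))
  invisible(x)
}

#' Selected (non-zero loading) features of an sPLS-DA component
#' @param model `SplsdaModel`.
#' @param comp component index.
#' @return character vector of feature ids.
#' @export
selected_features <- function(model, comp = 1) {
  rownames(model$x_weights)[model$x_weights[, comp] != 0]
}

#' Predict classes with an sPLS-DA model (max-distance rule)
#'
#' New samples are centered and scaled with the training parameters,
#' dummy-response predictions are formed from the model's regression
#' coefficients, and each sample is assigned to the class with the largest
#' predicted dummy value; exact ties go to the first class in
#' `model$class_map`.
#'
#' @param model `SplsdaModel`.
#' @param xnew matrix or [expression_matrix()] whose features are a
#'   superset of the model's features.
#' @param method prediction rule; only `"max_dist"` is implemented.
#' @return list with `class` (factor) and `scores` (n x 2 dummy
#'   predictions).
#' @export
predict_splsda <- function(model, xnew, method = c("max_dist")) {
  method <- match.arg(method)
  V <- get_values(xnew)
  feats <- rownames(model$x_weights)
  missing <- setdiff(feats, colnames(V))
  if (length(missing)) {
    stop("feature(s) absent from new data: ", paste(missing, collapse = ", "))
  }
  V <- V[, feats, drop = FALSE]
  Vs <- scale(V, center = model$x_center, scale = model$x_scale)
  Yhat <- Vs %*% model$coefficients
  Yhat <- sweep(Yhat, 2, model$y_center, `+`)
  colnames(Yhat) <- model$class_map
  idx <- apply(Yhat, 1, which.max)   # which.max takes the first on ties
  cls <- factor(model$class_map[idx], levels = model$class_map)
  names(cls) <- rownames(V)
  list(class = cls, scores = Yhat)
}

#' Tune sPLS-DA by stratified cross-validated error rate
#'
#' For each component h = 1..`max_ncomp` in turn, grid-searches the number
#' of variables `keepX[h]` minimizing the overall cross-validated
#' misclassification rate under max-distance prediction, with the earlier
#' components' keepX held at their chosen values. Ties are broken toward
#' smaller keepX; the returned `best_ncomp` is the dimension with the
#' lowest achieved error (ties toward fewer components). Fold assignment
#' is stratified by class and derived from `seed`.
#'
#' @param x,y data and labels as in [fit_splsda()].
#' @param max_ncomp maximum dimensions to examine (default 10).
#' @param keepX_grid candidate variable counts per component (default
#'   1..50).
#' @param folds number of CV folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @return list with `best_ncomp`, `best_keepX` (length `best_ncomp`),
#'   `keepX_path` (length `max_ncomp`), `error_rate` (max_ncomp x grid
#'   matrix) and `best_error` per dimension.
#' @export
tune_splsda <- function(x, y, max_ncomp = 10, keepX_grid = 1:50,
                        folds = 10, seed = 1) {
  X <- get_values(x)
  lab <- if (inherits(y, "ClassLabels")) align_labels(x, y) else factor(y)
  if (folds < 2) stop("`folds` must be >= 2")
  keepX_grid <- sort(unique(as.integer(keepX_grid)))
  keepX_grid <- keepX_grid[keepX_grid >= 1 & keepX_grid <= ncol(X)]
  fold_id <- stratified_folds(lab, folds, seed)
  for (f in seq_len(folds)) {
    if (nlevels(droplevels(lab[fold_id != f])) < 2) {
      stop("a training fold is missing one class; use stratified labels ",
           "or fewer folds")
    }
  }
  max_ncomp <- min(max_ncomp, min(nrow(X) - 1, ncol(X)))
  err <- matrix(NA_real_, max_ncomp, length(keepX_grid),
                dimnames = list(paste0("comp", seq_len(max_ncomp)),
                                as.character(keepX_grid)))
  keep_path <- integer(0)
  best_err <- numeric(max_ncomp)
  for (h in seq_len(max_ncomp)) {
    for (gi in seq_along(keepX_grid)) {
      kx <- c(keep_path, keepX_grid[gi])
      nerr <- 0
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        if (!any(!tr)) next
        fit <- fit_splsda(X[tr, , drop = FALSE], lab[tr], ncomp = h,
                          keepX = kx)
        pr <- predict_splsda(fit, X[!tr, , drop = FALSE])
        nerr <- nerr + sum(pr$class != lab[!tr])
      }
      err[h, gi] <- nerr / nrow(X)
    }
    gi_best <- which.min(err[h, ])          # first minimum = smallest keepX
    keep_path <- c(keep_path, keepX_grid[gi_best])
    best_err[h] <- err[h, gi_best]
  }
  best_ncomp <- which.min(best_err)          # first minimum = fewer comps
  list(best_ncomp = best_ncomp,
       best_keepX = keep_path[seq_len(best_ncomp)],
       keepX_path = keep_path,
       error_rate = err,
       best_error = best_err)
}

# deterministic stratified fold assignment
stratified_folds <- function(lab, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  id <- integer(length(lab))
  for (lv in levels(lab)) {
    idx <- sample(which(lab == lv))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' Per-component explained variance of an sPLS-DA model
#'
#' Fraction of the total centered-and-scaled X variance captured by each
#' component's rank-one reconstruction; with regression-mode deflation the
#' scores are orthogonal, so the cumulative value is the sum of the parts.
#'
#' @param model `SplsdaModel`.
#' @return list with `per_component` and `cumulative` fractions.
#' @export
explained_variance <- function(model) {
  list(per_component = model$explained_variance_x,
       cumulative = model$cum_explained_variance_x)
}
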