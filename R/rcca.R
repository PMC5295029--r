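#' Regularized canonical correlation analysis
#'
#' Classical CCA maximizes the correlation of paired linear projections of
#' two blocks measured on the same samples; with far more features than
#' samples the within-block covariances are singular, so each is ridged by
#' adding a multiple of the identity: `Cov(X) + lambda1 I` and
#' `Cov(Z) + lambda2 I`. Dimensions are extracted from the symmetric
#' generalized-eigenvalue form; weights are normalized so every variate
#' has unit variance and oriented so paired variates correlate
#' positively.
#'
#' Features are centered and (by default) scaled to unit variance, the
#' convention under which correlation-circle projections live in the unit
#' disc.
#'
#' @param x,z [expression_matrix()] objects or samples x features matrices
#'   on the same samples (same row order).
#' @param lambda1,lambda2 non-negative ridge penalties. With a penalty of
#'   0 the corresponding covariance must be non-singular.
#' @param ncomp number of dimensions to extract (default
#'   `min(p, q, n - 1)`).
#' @param scale. scale features to unit variance (default TRUE).
#' @return `RccaModel`: `canonical_correlations` (correlations of paired
#'   variates, non-increasing), `x_weights`/`z_weights`,
#'   `x_variates`/`z_variates` (n x ncomp, unit variance), penalties, and
#'   centering/scaling parameters.
#' @export
fit_rcca <- function(x, z, lambda1 = 0, lambda2 = 0, ncomp = NULL,
                     scale. = TRUE) {
  X <- get_values(x); Z <- get_values(z)
  if (nrow(X) != nrow(Z)) stop("x and z must have the same samples")
  if (!is.null(rownames(X)) && !is.null(rownames(Z)) &&
      !identical(rownames(X), rownames(Z))) {
    stop("x and z sample ids differ or are ordered differently")
  }
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be >= 0")
  n <- nrow(X); p <- ncol(X); q <- ncol(Z)
  Xc <- scale(X, scale = scale.); Zc <- scale(Z, scale = scale.)
  if (any(!is.finite(Xc)) || any(!is.finite(Zc))) {
    stop("constant feature produced non-finite scaled values")
  }
  Sxx <- crossprod(Xc) / (n - 1) + diag(lambda1, p)
  Szz <- crossprod(Zc) / (n - 1) + diag(lambda2, q)
  Sxz <- crossprod(Xc, Zc) / (n - 1)

  ex <- eigen(Sxx, symmetric = TRUE)
  ez <- eigen(Szz, symmetric = TRUE)
  tol <- 1e-10
  if (min(ex$values) < tol || min(ez$values) < tol) {
    stop("within-block covariance is singular at this penalty; ",
         "use lambda > 0")
  }
  Sxx_isqrt <- ex$vectors %*% (t(ex$vectors) / sqrt(ex$values))
  Szz_inv <- ez$vectors %*% (t(ez$vectors) / ez$values)

  Kmat <- Sxx_isqrt %*% Sxz
  M <- Kmat %*% Szz_inv %*% t(Kmat)
  em <- eigen((M + t(M)) / 2, symmetric = TRUE)
  dmax <- min(p, q, n - 1)
  if (is.null(ncomp)) ncomp <- dmax
  ncomp <- min(ncomp, dmax)

  A <- Sxx_isqrt %*% em$vectors[, seq_len(ncomp), drop = FALSE]
  B <- Szz_inv %*% t(Sxz) %*% A
  Tx <- Xc %*% A
  Tz <- Zc %*% B
  # unit-variance variates; orient pairs to positive correlation
  for (h in seq_len(ncomp)) {
    sx <- stats::sd(Tx[, h]); sz <- stats::sd(Tz[, h])
    if (sx > 0) { A[, h] <- A[, h] / sx; Tx[, h] <- Tx[, h] / sx }
    if (sz > 0) { B[, h] <- B[, h] / sz; Tz[, h] <- Tz[, h] / sz }
    if (stats::cor(Tx[, h], Tz[, h]) < 0) {
      B[, h] <- -B[, h]; Tz[, h] <- -Tz[, h]
    }
    # deterministic overall sign: largest-|weight| x entry positive
    if (A[which.max(abs(A[, h])), h] < 0) {
      A[, h] <- -A[, h]; Tx[, h] <- -Tx[, h]
      B[, h] <- -B[, h]; Tz[, h] <- -Tz[, h]
    }
  }
  cors <- vapply(seq_len(ncomp), function(h)
    stats::cor(Tx[, h], Tz[, h]), numeric(1))

  rownames(A) <- colnames(X); rownames(B) <- colnames(Z)
  rownames(Tx) <- rownames(X); rownames(Tz) <- rownames(X)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 canonical_correlations = cors,
                 x_weights = A, z_weights = B,
                 x_variates = Tx, z_variates = Tz,
                 ncomp = ncomp, scale = scale.),
            class = "RccaModel")
}

#' @export
print.RccaModel <- function(x, ...) {
  cat(sprintf("RccaModel: lambda = (%g, %g), %d dimension(s), rho1 = %.3f\n",
              x$lambda1, x$lambda2, x$ncomp,
              x$canonical_correlations[1]))
  invisible(x)
}

#' Tune the rCCA ridge penalties by cross-validation
#'
#' For every grid pair (lambda1, lambda2) the cross-validation score is
#' the mean over folds of the correlation between the held-out first
#' variates computed with the training-fold weights; the pair maximizing
#' the score is returned (ties toward smaller penalties). The default
#' grids place 100 evenly spaced points strictly inside (0.001, 0.05) and
#' (0.0001, 0.05).
#'
#' @param x,z paired blocks as in [fit_rcca()].
#' @param grid1,grid2 candidate penalty values.
#' @param folds number of CV folds (default 10); every fold must hold out
#'   at least 3 samples so a correlation is defined.
#' @param seed integer seed for the fold assignment.
#' @param scale. passed to [fit_rcca()].
#' @return list with `lambda1`, `lambda2`, and the full `cv_score`
#'   surface (grid1 x grid2).
#' @export
tune_rcca <- function(x, z,
                      grid1 = seq(0.001, 0.05,
                                  length.out = 102)[2:101],
                      grid2 = seq(0.0001, 0.05,
                                  length.out = 102)[2:101],
                      folds = 10, seed = 1, scale. = TRUE) {
  X <- get_values(x); Z <- get_values(z)
  if (!length(grid1) || !length(grid2)) stop("penalty grids must be non-empty")
  n <- nrow(X)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  fold_id <- rep_len(seq_len(folds), n)[sample.int(n)]
  if (min(table(fold_id)) < 3) {
    stop("a fold holds out fewer than 3 samples; ",
         "a held-out correlation is undefined - use fewer folds")
  }
  score <- matrix(NA_real_, length(grid1), length(grid2),
                  dimnames = list(format(grid1), format(grid2)))
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      sc <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- fit_rcca(X[tr, , drop = FALSE], Z[tr, , drop = FALSE],
                        grid1[i], grid2[j], ncomp = 1, scale. = scale.)
        ctr <- colMeans(X[tr, , drop = FALSE])
        czr <- colMeans(Z[tr, , drop = FALSE])
        sx <- if (scale.) apply(X[tr, , drop = FALSE], 2, stats::sd) else 1
        sz <- if (scale.) apply(Z[tr, , drop = FALSE], 2, stats::sd) else 1
        u <- scale(X[!tr, , drop = FALSE], ctr, sx) %*% fit$x_weights[, 1]
        v <- scale(Z[!tr, , drop = FALSE], czr, sz) %*% fit$z_weights[, 1]
        if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
        stats::cor(u, v)[1, 1]
      }, numeric(1))
      score[i, j] <- mean(sc)
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)
  # ties toward smaller penalties (grids are ascending)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(lambda1 = grid1[best[1]], lambda2 = grid2[best[2]],
       cv_score = score)
}

#' Choose the number of rCCA dimensions from the correlation profile
#'
#' Empirical gap rule: the retained dimension count is the index just
#' before the largest consecutive drop in the canonical correlations. If
#' all consecutive drops are (numerically) equal there is no clear gap;
#' 1 is returned with a warning.
#'
#' @param canonical_correlations numeric vector (length >= 2).
#' @param override optional manual dimension choice; honored (and
#'   reported via a message) when supplied.
#' @return integer dimension count `d`.
#' @export
select_dimensions <- function(canonical_correlations, override = NULL) {
  cc <- canonical_correlations
  if (length(cc) < 2) stop("need at least 2 canonical correlations")
  if (!is.null(override)) {
    message("dimension override honored: d = ", override)
    return(as.integer(override))
  }
  drops <- -diff(cc)
  if (length(drops) > 1 && diff(range(drops)) < 1e-8) {
    warning("no clear gap among canonical correlations; returning d = 1")
    return(1L)
  }
  which.max(drops)
}

#' Correlation-circle coordinates of the retained features
#'
#' Projects every feature of both blocks onto the first two rCCA
#' dimensions as its Pearson correlation with each dimension's compromise
#' variate (the mean of the x- and z-variate). Features whose radius
#' (Euclidean norm over dimensions 1-2) exceeds `inner_radius` are
#' retained; the rest are considered uninformative and dropped.
#'
#' @param model fitted `RccaModel` (>= 2 dimensions).
#' @param x,z the data blocks the model was fitted on.
#' @param inner_radius retention radius in (0, 1); default 0.3.
#' @return data frame of `CirclePoint`s: `feature_id`, `block`
#'   (mirna/gene), `dim1`, `dim2`, `radius`, sorted by block then id.
#' @export
correlation_circle <- function(model, x, z, inner_radius = 0.3) {
  if (inner_radius <= 0 || inner_radius >= 1) {
    stop("`inner_radius` must lie in (0, 1)")
  }
  if (model$ncomp < 2) stop("model needs at least 2 dimensions")
  X <- get_values(x); Z <- get_values(z)
  comp <- (model$x_variates[, 1:2] + model$z_variates[, 1:2]) / 2
  cx <- stats::cor(X, comp)
  cz <- stats::cor(Z, comp)
  pts <- rbind(
    data.frame(feature_id = colnames(X), block = "mirna",
               dim1 = cx[, 1], dim2 = cx[, 2], stringsAsFactors = FALSE),
    data.frame(feature_id = colnames(Z), block = "gene",
               dim1 = cz[, 1], dim2 = cz[, 2], stringsAsFactors = FALSE))
  pts$radius <- sqrt(pts$dim1^2 + pts$dim2^2)
  pts <- pts[pts$radius > inner_radius, , drop = FALSE]
  pts <- pts[order(pts$block, pts$feature_id), , drop = FALSE]
  rownames(pts) <- NULL
  pts
}

#' Cross-block similarity matrix and bi-clustering (CIM)
#'
#' The similarity of a retained miRNA i and gene j is the inner product of
#' their correlation-circle coordinates over the retained dimensions, the
#' quantity a clustered image map displays. Rows (miRNAs) and columns
#' (genes) are ordered by hierarchical clustering of the coordinate
#' vectors with Euclidean distance and average linkage.
#'
#' @param points data frame from [correlation_circle()] containing both
#'   blocks.
#' @return list with `similarity` (miRNA x gene), `row_order`,
#'   `col_order`, and the two `hclust` objects (`NULL` for singleton
#'   blocks).
#' @export
cim_similarity <- function(points) {
  mir <- points[points$block == "mirna", , drop = FALSE]
  gen <- points[points$block == "gene", , drop = FALSE]
  if (!nrow(mir) || !nrow(gen)) {
    stop("need at least one retained feature per block")
  }
  Mi <- as.matrix(mir[, c("dim1", "dim2")]); rownames(Mi) <- mir$feature_id
  Ge <- as.matrix(gen[, c("dim1", "dim2")]); rownames(Ge) <- gen$feature_id
  S <- Mi %*% t(Ge)
  hr <- if (nrow(Mi) > 1) stats::hclust(stats::dist(Mi), method = "average")
        else NULL
  hc <- if (nrow(Ge) > 1) stats::hclust(stats::dist(Ge), method = "average")
        else NULL
  list(similarity = S,
       row_order = if (is.null(hr)) 1L else hr$order,
       col_order = if (is.null(hc)) 1L else hc$order,
       row_hclust = hr, col_hclust = hc)
}
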