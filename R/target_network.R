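#' Keep the top-variance fraction of genes
#'
#' Ranks genes by their across-sample variance and retains the top
#' `ceiling(fraction * q)`; ties at the cut go to the lexicographically
#' lower feature id.
#'
#' @param z [expression_matrix()] or samples x genes matrix.
#' @param fraction proportion in (0, 1]; default 0.75.
#' @return character vector of retained gene ids (original column order
#'   is not preserved; ids are returned in rank order).
#' @export
variance_top_fraction <- function(z, fraction = 0.75) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must lie in (0, 1]")
  Z <- get_values(z)
  v <- apply(Z, 2, stats::var)
  ord <- order(-v, colnames(Z))
  colnames(Z)[ord[seq_len(ceiling(fraction * ncol(Z)))]]
}

#' All-pairs miRNA-gene anticorrelation tests
#'
#' Pearson correlation of every miRNA-gene pair across samples, with a
#' one-sided p-value for the negative tail (the biological hypothesis is
#' that a miRNA represses its target's transcript) via the t-transform of
#' r on n - 2 degrees of freedom, and BH q-values over all tested pairs.
#' Pairs involving a constant vector are skipped with a message.
#'
#' @param x_sel,z_sel matrices or [expression_matrix()] objects on the
#'   same samples (>= 4).
#' @param alternative `"less"` (default, negative tail) or `"two.sided"`.
#' @return data frame (`mirna`, `gene`, `r`, `p`, `q`), one row per
#'   tested pair.
#' @export
pairwise_anticorrelation <- function(x_sel, z_sel,
                                     alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  X <- get_values(x_sel); Z <- get_values(z_sel)
  if (nrow(X) != nrow(Z)) stop("blocks must share samples")
  n <- nrow(X)
  if (n < 4) stop("need at least 4 samples")
  okx <- apply(X, 2, stats::sd) > 0
  okz <- apply(Z, 2, stats::sd) > 0
  if (any(!okx) || any(!okz)) {
    message("skipping constant feature(s): ",
            paste(c(colnames(X)[!okx], colnames(Z)[!okz]), collapse = ", "))
  }
  X <- X[, okx, drop = FALSE]; Z <- Z[, okz, drop = FALSE]
  R <- stats::cor(X, Z)
  r <- as.vector(R)
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- if (alternative == "less") stats::pt(tstat, df = n - 2)
       else 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- data.frame(
    mirna = rep(colnames(X), times = ncol(Z)),
    gene = rep(colnames(Z), each = ncol(X)),
    r = r, p = p, q = bh_fdr(p),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consensus of target-prediction databases
#'
#' Union of the databases' directed miRNA-gene edges annotated with the
#' number of databases supporting each edge, filtered to support >=
#' `min_support` (default 2 of 3).
#'
#' @param dbs list of [target_prediction_set()] objects.
#' @param min_support minimum database count, in 1..length(dbs).
#' @return data frame (`mirna`, `gene`, `db_support`).
#' @export
consensus_predictions <- function(dbs, min_support = 2) {
  if (!length(dbs)) stop("no databases supplied")
  if (min_support < 1 || min_support > length(dbs)) {
    stop("`min_support` must lie in 1..", length(dbs))
  }
  empt <- vapply(dbs, function(d) nrow(d$edges) == 0, logical(1))
  if (any(empt)) {
    warning("empty database(s): ", paste(vapply(
      dbs[empt], `[[`, character(1), "database_name"), collapse = ", "))
  }
  all_edges <- do.call(rbind, lapply(dbs, function(d) d$edges))
  if (is.null(all_edges) || !nrow(all_edges)) {
    return(data.frame(mirna = character(0), gene = character(0),
                      db_support = integer(0), stringsAsFactors = FALSE))
  }
  key <- paste(all_edges$mirna, all_edges$gene, sep = "\r")
  tab <- table(key)
  keep <- names(tab)[tab >= min_support]
  parts <- strsplit(keep, "\r", fixed = TRUE)
  out <- data.frame(
    mirna = vapply(parts, `[[`, character(1), 1),
    gene = vapply(parts, `[[`, character(1), 2),
    db_support = as.integer(tab[keep]),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the integrated anticorrelation x prediction network
#'
#' The integrated network's edges are exactly the intersection of the
#' database-consensus predictions with the anticorrelated pairs passing
#' `q < max_q` and `r < 0`. Nodes are the endpoints of surviving edges;
#' isolated features are excluded.
#'
#' @param anticorr data frame from [pairwise_anticorrelation()].
#' @param consensus data frame from [consensus_predictions()].
#' @param max_q q-value threshold (default 0.1, strict `<`).
#' @return `IntegratedNetwork`: list with `edges` (mirna, gene, r, p, q,
#'   db_support), `mirnas`, `genes`.
#' @export
build_integrated_network <- function(anticorr, consensus, max_q = 0.1) {
  sig <- anticorr[anticorr$q < max_q & anticorr$r < 0, , drop = FALSE]
  edges <- merge(sig, consensus, by = c("mirna", "gene"))
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges)) {
    warning("integrated network is empty under the current thresholds")
  }
  structure(list(edges = edges,
                 mirnas = sort(unique(edges$mirna)),
                 genes = sort(unique(edges$gene))),
            class = "IntegratedNetwork")
}

#' @export
print.IntegratedNetwork <- function(x, ...) {
  cat(sprintf("IntegratedNetwork: %d miRNAs, %d genes, %d interactions\n",
              length(x$mirnas), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Hub statistics of an integrated network
#'
#' Node degrees, the fraction of all interactions accounted for by the
#' `top_k` highest-degree miRNAs (degree ties ranked by node id), and the
#' genes co-targeted by at least `min_cotarget` miRNAs.
#'
#' @param net `IntegratedNetwork` (non-empty).
#' @param top_k number of hub miRNAs to aggregate (default 4).
#' @param min_cotarget co-targeting threshold (default 8).
#' @return list with `degrees` (data frame: node, block, degree),
#'   `top_mirnas`, `coverage` (fraction of edges touching the top_k
#'   miRNAs), and `cotargeted_genes`.
#' @export
hub_statistics <- function(net, top_k = 4, min_cotarget = 8) {
  if (!nrow(net$edges)) stop("network is empty")
  dm <- table(net$edges$mirna)
  dg <- table(net$edges$gene)
  degrees <- rbind(
    data.frame(node = names(dm), block = "mirna",
               degree = as.integer(dm), stringsAsFactors = FALSE),
    data.frame(node = names(dg), block = "gene",
               degree = as.integer(dg), stringsAsFactors = FALSE))
  ord <- order(-as.integer(dm), names(dm))
  top <- names(dm)[ord][seq_len(min(top_k, length(dm)))]
  coverage <- sum(net$edges$mirna %in% top) / nrow(net$edges)
  cotarg <- names(dg)[as.integer(dg) >= min_cotarget]
  list(degrees = degrees, top_mirnas = top, coverage = coverage,
       cotargeted_genes = sort(cotarg))
}
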