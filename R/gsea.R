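#' Rank genes by Pearson correlation with a continuous trait
#'
#' Computes each gene's Pearson correlation with a per-sample trait (for
#' this pipeline, typically an sPLS-DA component score) and returns genes
#' sorted by decreasing correlation, ties broken by gene id. Constant
#' genes get r = 0 with a warning; a constant trait is an error.
#'
#' @param z [expression_matrix()] or samples x genes matrix.
#' @param trait numeric vector, one value per sample (matrix row order).
#' @return data frame (`gene_id`, `score`) sorted by decreasing score.
#' @export
rank_by_trait_correlation <- function(z, trait) {
  Z <- get_values(z)
  if (length(trait) != nrow(Z)) stop("`trait` length must equal n samples")
  if (stats::sd(trait) == 0) stop("`trait` is constant; correlation undefined")
  sds <- apply(Z, 2, stats::sd)
  r <- rep(0, ncol(Z))
  if (any(sds == 0)) {
    warning("constant gene(s) assigned r = 0: ",
            paste(colnames(Z)[sds == 0], collapse = ", "))
  }
  ok <- sds > 0
  r[ok] <- drop(stats::cor(Z[, ok, drop = FALSE], trait))
  out <- data.frame(gene_id = colnames(Z), score = r,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene_id), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

#' Weighted running-sum enrichment score
#'
#' Standard weighted Kolmogorov-Smirnov-like statistic over a ranked gene
#' list: walking down the ranking, hits increment the running sum by
#' `|score|^weight_exponent` (normalized over the set's hits) and misses
#' decrement it by `1/(N - N_hits)`; the enrichment score is the signed
#' maximum deviation from zero.
#'
#' @param ranked data frame from [rank_by_trait_correlation()] (columns
#'   `gene_id`, `score`, already sorted).
#' @param gene_set character vector of member gene ids.
#' @param weight_exponent weighting of hit increments by |score| (default
#'   1, the conventional weighted statistic; 0 gives the unweighted KS
#'   walk).
#' @return list with `es`, `position` of the extremum, the full
#'   `running_sum`, and the `leading_edge` member ids.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  ids <- ranked$gene_id
  N <- length(ids)
  hit <- ids %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has no overlap with the ranked list")
  if (nh == N) stop("gene set covers the whole ranked list; ",
                    "miss increment undefined")
  rs <- es_walk(ranked$score, hit, weight_exponent, running = TRUE)
  es <- es_extremum(rs)
  pos <- if (es >= 0) which.max(rs) else which.min(rs)
  le <- if (es >= 0) ids[seq_len(pos)][hit[seq_len(pos)]]
        else ids[seq.int(pos, N)][hit[seq.int(pos, N)]]
  list(es = es, position = pos, running_sum = rs, leading_edge = le)
}

# weighted KS running sum over a sorted score vector; returns the signed
# maximum deviation (or the whole walk)
es_walk <- function(score_sorted, hit, weight_exponent, running = FALSE) {
  N <- length(score_sorted)
  nh <- sum(hit)
  w <- abs(score_sorted)^weight_exponent
  inc <- rep(-1 / (N - nh), N)
  sw <- sum(w[hit])
  inc[hit] <- if (sw > 0) w[hit] / sw else 1 / nh
  rs <- cumsum(inc)
  if (running) return(rs)
  es_extremum(rs)
}

# signed maximum deviation; near-ties (within 1e-12) resolve to the
# positive extremum so the statistic is deterministic under exact
# symmetric walks
es_extremum <- function(rs) {
  hi <- max(rs); lo <- min(rs)
  if (hi + 1e-12 >= -lo) hi else lo
}

#' Trait GSEA with phenotype permutation
#'
#' For each gene set, computes the enrichment score against the observed
#' trait ranking and builds the null by permuting the continuous trait
#' vector across samples (phenotype permutation), re-ranking and
#' re-scoring per permutation. Nominal p-values use same-sign permuted
#' scores with the add-one convention; NES divides each score by the mean
#' same-sign permuted |ES|; FDR q follows the standard NES-based
#' procedure. Sets are intersected with the genes present in `z`, then
#' size-filtered.
#'
#' @param z samples x genes matrix or [expression_matrix()].
#' @param trait numeric per-sample trait.
#' @param sets [gene_set_collection()].
#' @param n_perm number of trait permutations (>= 100).
#' @param weight_exponent see [enrichment_score()].
#' @param min_size,max_size set-size bounds after intersection (defaults
#'   10 and 500); out-of-range sets are dropped with a message.
#' @param seed integer seed.
#' @param fdr_threshold reporting threshold; retained sets flagged at
#'   q < this value (default 0.05).
#' @return `EnrichmentResult` data frame: per set `es`, `nes`, `p`, `q`,
#'   `size`, `z_score`, `direction`, `significant`, and the leading edge
#'   as a comma-joined string.
#' @export
gsea_phenotype_permutation <- function(z, trait, sets, n_perm = 1000,
                                       weight_exponent = 1,
                                       min_size = 10, max_size = 500,
                                       seed = 1, fdr_threshold = 0.05) {
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  Z <- get_values(z)
  universe <- colnames(Z)
  kept <- lapply(sets$sets, intersect, x = universe)
  sizes <- lengths(kept)
  drop <- sizes < min_size | sizes > max_size
  if (any(drop)) {
    message("dropping ", sum(drop), " set(s) outside size bounds: ",
            paste(names(kept)[drop], collapse = ", "))
  }
  kept <- kept[!drop]
  if (!length(kept)) stop("no gene set left after size filtering")

  ranked <- rank_by_trait_correlation(Z, trait)
  obs <- lapply(kept, function(s)
    enrichment_score(ranked, s, weight_exponent))
  es_obs <- vapply(obs, `[[`, numeric(1), "es")

  # permutation loop on a vectorized path (same walk as enrichment_score)
  ok <- apply(Z, 2, stats::sd) > 0
  Zok <- Z[, ok, drop = FALSE]
  ids_ok <- colnames(Zok)
  hit_tpl <- lapply(kept, function(s) ids_ok %in% s)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  es_perm <- matrix(NA_real_, length(kept), n_perm,
                    dimnames = list(names(kept), NULL))
  for (b in seq_len(n_perm)) {
    r <- drop(stats::cor(Zok, sample(trait)))
    ord <- order(-r, ids_ok)
    r_sorted <- r[ord]
    for (si in seq_along(kept)) {
      es_perm[si, b] <- es_walk(r_sorted, hit_tpl[[si]][ord],
                                weight_exponent)
    }
  }

  pos_mean <- apply(es_perm, 1, function(v) mean(abs(v[v >= 0])))
  neg_mean <- apply(es_perm, 1, function(v) mean(abs(v[v < 0])))
  nes_obs <- ifelse(es_obs >= 0, es_obs / pos_mean, -abs(es_obs) / neg_mean)
  nes_obs[!is.finite(nes_obs)] <- 0
  nes_perm <- es_perm
  for (si in seq_along(kept)) {
    v <- es_perm[si, ]
    nes_perm[si, ] <- ifelse(v >= 0, v / pos_mean[si], -abs(v) / neg_mean[si])
  }
  nes_perm[!is.finite(nes_perm)] <- 0

  p_nom <- vapply(seq_along(kept), function(si) {
    v <- es_perm[si, ]
    if (es_obs[si] >= 0) {
      (1 + sum(v[v >= 0] >= es_obs[si])) / (1 + sum(v >= 0))
    } else {
      (1 + sum(v[v < 0] <= es_obs[si])) / (1 + sum(v < 0))
    }
  }, numeric(1))

  # NES-based FDR (positive and negative tails handled separately)
  all_perm <- as.vector(nes_perm)
  q <- vapply(seq_along(kept), function(si) {
    s <- nes_obs[si]
    if (s >= 0) {
      num <- mean(all_perm >= s & all_perm >= 0) /
        max(mean(all_perm >= 0), 1e-12)
      den <- sum(nes_obs >= s) / max(sum(nes_obs >= 0), 1L)
    } else {
      num <- mean(all_perm <= s & all_perm < 0) /
        max(mean(all_perm < 0), 1e-12)
      den <- sum(nes_obs <= s) / max(sum(nes_obs < 0), 1L)
    }
    min(1, num / den)
  }, numeric(1))

  zsc <- vapply(seq_along(kept), function(si) {
    members <- kept[[si]]
    sc <- ranked$score[match(members, ranked$gene_id)]
    goplot_zscore(sc > 0)
  }, numeric(1))

  out <- data.frame(
    set = names(kept),
    size = lengths(kept),
    es = es_obs, nes = nes_obs, p = p_nom, q = q,
    minus_log10_p = -log10(p_nom),
    z_score = zsc,
    direction = ifelse(es_obs >= 0, "positive", "negative"),
    significant = q < fdr_threshold,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Bubble-plot z-score of a gene set
#'
#' `z = (n_up - n_down) / sqrt(n_up + n_down)` over the set's members,
#' where "up" means positive trait correlation. The two bubble-plot axes
#' (this z-score and -log10 p) are emitted as columns of the enrichment
#' table; rendering is left to the caller.
#'
#' @param up logical vector, one entry per set member (`TRUE` = positively
#'   correlated with the trait).
#' @return the z-score.
#' @export
goplot_zscore <- function(up) {
  if (!length(up)) stop("empty gene set")
  (sum(up) - sum(!up)) / sqrt(length(up))
}
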