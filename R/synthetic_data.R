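#' Generate a paired miRNA/gene cohort with planted ground truth
#'
#' Simulates the study design this pipeline targets: two unbalanced outcome
#' classes (default 14 vs 26 samples), a miRNA block that separates the
#' classes univariately (component 1), a second block that is marginally
#' null but jointly discriminative (component 2), linear miRNA-to-target
#' repression for a small co-targeted signature (3 miRNAs x 5 genes by
#' default, every pair a true edge),
#' pathway-sized gene blocks driven by each component (so trait-GSEA has a
#' truly enriched set per component, plus size-matched null sets), and three
#' noisy target-prediction databases containing each true edge with
#' per-database sensitivity `tpr` and each random non-edge with false
#' positive rate `fpr`.
#'
#' Expression values are Gaussian on the log2-intensity scale: feature
#' baselines are drawn from U(6, 12) and within-class noise has unit
#' standard deviation, so `effect_size` is a standardized mean shift.
#' Component-1 miRNAs are shifted up in class1 ("short"). Component-2
#' miRNAs come in pairs sharing a latent N(0, 20^2) factor; class1 samples
#' are additionally shifted by +/- `effect_size` along the within-pair
#' contrast, which leaves each miRNA's marginal two-sample t approximately
#' null while the pair difference separates the classes.
#'
#' Each target gene equals `baseline - repression_slope * miRNA +
#' N(0, noise_sd^2)`, giving the negative miRNA-target correlation the
#' integration stage searches for. Non-target genes are independent noise.
#'
#' @param n_class0,n_class1 samples per class (class0 = "long",
#'   class1 = "short").
#' @param p_mirna,q_gene total feature counts.
#' @param effect_size standardized between-class shift of component-1
#'   miRNAs (and, doubled, of the component-2 pair contrast); must be >= 0.
#' @param repression_slope linear repression coefficient of signature
#'   target genes on their miRNA.
#' @param noise_sd residual standard deviation of target genes; must be > 0.
#' @param n_comp1,n_comp2 planted component sizes (miRNAs); `n_comp2` must
#'   be even (pairs).
#' @param n_signature_mirna,n_signature_gene size of the planted
#'   repression signature; signature miRNAs are the first
#'   `n_signature_mirna` component-1 miRNAs.
#' @param n_pathway_gene genes per component-driven pathway block (one
#'   truly enriched gene set per component).
#' @param n_null_sets number of size-matched random gene sets.
#' @param tpr,fpr length-3 per-database true-positive and false-positive
#'   rates for the simulated prediction databases.
#' @param detect_rate per-cell detection probability for expressed miRNAs;
#'   `low_detect_frac` of background miRNAs instead use `low_detect_rate`,
#'   so the 10% detection filter has something to remove.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return A list of class `SyntheticCohort` with elements `mirna` and
#'   `gene` ([expression_matrix()]), `labels` ([class_labels()]),
#'   `gene_sets` ([gene_set_collection()]), `db_edges` (list of three
#'   [target_prediction_set()]), and `truth` (`SyntheticTruth`: planted
#'   component memberships, target edges with slopes, enriched set names,
#'   database rates, class assignment).
#' @export
generate_cohort <- function(n_class0 = 14, n_class1 = 26,
                            p_mirna = 614, q_gene = 2000,
                            effect_size = 2, repression_slope = 1,
                            noise_sd = 0.5,
                            n_comp1 = 10, n_comp2 = 10,
                            n_signature_mirna = 3, n_signature_gene = 5,
                            n_pathway_gene = 40, n_null_sets = 8,
                            tpr = c(0.8, 0.8, 0.8),
                            fpr = c(0.02, 0.02, 0.02),
                            detect_rate = 0.95,
                            low_detect_frac = 0.02, low_detect_rate = 0.05,
                            seed = 1) {
  if (n_class0 < 2 || n_class1 < 2) stop("each class needs >= 2 samples")
  if (effect_size < 0) stop("`effect_size` must be >= 0")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (n_comp2 %% 2 != 0) stop("`n_comp2` must be even (paired construction)")
  if (n_signature_mirna > n_comp1) {
    stop("`n_signature_mirna` cannot exceed `n_comp1`")
  }
  if (length(tpr) != 3 || length(fpr) != 3) stop("`tpr`/`fpr` must be length 3")
  if (p_mirna < n_comp1 + n_comp2 + 2) stop("`p_mirna` too small")
  if (q_gene < n_signature_gene + 2 * n_pathway_gene +
      n_null_sets * n_pathway_gene) {
    stop("`q_gene` too small for the planted gene blocks and null sets")
  }

  n <- n_class0 + n_class1
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  samp <- sprintf("S%03d", seq_len(n))
  lab <- factor(rep(c("long", "short"), c(n_class0, n_class1)),
                levels = c("long", "short"))
  cls1 <- as.numeric(lab == "short")

  mir_ids <- sprintf("syn-miR-%04d", seq_len(p_mirna))
  gene_ids <- sprintf("SYNG%05d", seq_len(q_gene))

  comp1 <- mir_ids[seq_len(n_comp1)]
  comp2 <- mir_ids[n_comp1 + seq_len(n_comp2)]
  sig_mirna <- comp1[seq_len(n_signature_mirna)]

  # --- miRNA matrix ---------------------------------------------------
  mir_base <- stats::runif(p_mirna, 6, 12)
  X <- matrix(stats::rnorm(n * p_mirna), n, p_mirna,
              dimnames = list(samp, mir_ids))
  X <- sweep(X, 2, mir_base, `+`)
  # component 1: standardized shift up in class1
  X[, comp1] <- X[, comp1] + effect_size * cls1
  # component 2: pairs share a large latent factor; class1 shifted along
  # the within-pair contrast (+/- effect_size), cancelling marginally
  comp2_shared_sd <- 20
  for (k in seq_len(n_comp2 / 2)) {
    u <- stats::rnorm(n, 0, comp2_shared_sd)
    j1 <- comp2[2 * k - 1]; j2 <- comp2[2 * k]
    X[, j1] <- X[, j1] + u + effect_size * cls1
    X[, j2] <- X[, j2] + u - effect_size * cls1
  }

  # detection flags: planted miRNAs always detected; a small tail of
  # background miRNAs is rarely detected
  n_low <- round(low_detect_frac * p_mirna)
  low_idx <- if (n_low > 0) seq.int(p_mirna - n_low + 1, p_mirna) else integer(0)
  det <- matrix(stats::runif(n * p_mirna) < detect_rate, n, p_mirna,
                dimnames = list(samp, mir_ids))
  if (length(low_idx)) {
    det[, low_idx] <- matrix(stats::runif(n * length(low_idx)) <
                               low_detect_rate, n, length(low_idx))
  }
  det[, c(comp1, comp2)] <- TRUE

  # --- gene matrix ----------------------------------------------------
  gene_base <- stats::runif(q_gene, 6, 12)
  Z <- matrix(stats::rnorm(n * q_gene), n, q_gene,
              dimnames = list(samp, gene_ids))
  Z <- sweep(Z, 2, gene_base, `+`)

  sig_gene <- gene_ids[seq_len(n_signature_gene)]
  # every signature gene is repressed by the whole signature miRNA set
  # (co-targeting hub topology: all miRNA x gene pairs are true edges)
  Mc <- scale(X[, sig_mirna, drop = FALSE], scale = FALSE)
  for (g in seq_len(n_signature_gene)) {
    Z[, sig_gene[g]] <- gene_base[g] -
      repression_slope * rowMeans(Mc) + stats::rnorm(n, 0, noise_sd)
  }

  # pathway blocks driven (negatively) by each component's summary
  path1 <- gene_ids[n_signature_gene + seq_len(n_pathway_gene)]
  path2 <- gene_ids[n_signature_gene + n_pathway_gene + seq_len(n_pathway_gene)]
  c1_score <- rowMeans(X[, comp1, drop = FALSE])
  c1_score <- (c1_score - mean(c1_score)) / stats::sd(c1_score)
  if (n_comp2 > 0) {
    odd <- comp2[seq(1, n_comp2, by = 2)]
    even <- comp2[seq(2, n_comp2, by = 2)]
    c2_score <- rowMeans(X[, odd, drop = FALSE]) -
      rowMeans(X[, even, drop = FALSE])
  } else {
    c2_score <- stats::rnorm(n)   # no component 2: null driver
  }
  c2_score <- (c2_score - mean(c2_score)) / stats::sd(c2_score)
  Z[, path1] <- Z[, path1] - c1_score
  Z[, path2] <- Z[, path2] - c2_score

  # gene sets: one truly enriched set per component + null sets
  sets <- list(PATHWAY_C1 = path1, PATHWAY_C2 = path2)
  null_pool <- gene_ids[-seq_len(n_signature_gene + 2 * n_pathway_gene)]
  for (k in seq_len(n_null_sets)) {
    sets[[sprintf("NULL_SET_%02d", k)]] <- sample(null_pool, n_pathway_gene)
  }
  gsc <- gene_set_collection(sets,
    description = c("targets of component-1 miRNAs",
                    "targets of component-2 miRNAs",
                    rep("random background genes", n_null_sets)))

  # --- target-prediction databases ------------------------------------
  true_edges <- expand.grid(mirna = sig_mirna, gene = sig_gene,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  true_edges$slope <- repression_slope
  true_edges <- true_edges[order(true_edges$mirna, true_edges$gene), ]
  rownames(true_edges) <- NULL
  true_key <- paste(true_edges$mirna, true_edges$gene)
  db_names <- c("dbA", "dbB", "dbC")
  db_edges <- vector("list", 3)
  total_pairs <- as.double(p_mirna) * q_gene
  for (k in 1:3) {
    keep_true <- stats::runif(nrow(true_edges)) < tpr[k]
    n_fp <- stats::rbinom(1, total_pairs - nrow(true_edges), fpr[k])
    # sample non-edge indices; drop collisions with true edges
    idx <- sample.int(total_pairs, min(n_fp + 50, total_pairs))
    mi <- ((idx - 1) %% p_mirna) + 1
    gi <- ((idx - 1) %/% p_mirna) + 1
    key <- paste(mir_ids[mi], gene_ids[gi])
    ok <- !(key %in% true_key)
    mi <- mi[ok][seq_len(min(n_fp, sum(ok)))]
    gi <- gi[ok][seq_len(min(n_fp, sum(ok)))]
    db_edges[[k]] <- target_prediction_set(
      db_names[k],
      c(true_edges$mirna[keep_true], mir_ids[mi]),
      c(true_edges$gene[keep_true], gene_ids[gi]))
  }
  names(db_edges) <- db_names

  truth <- structure(list(
    component1_mirnas = comp1,
    component2_mirnas = comp2,
    signature_mirnas = sig_mirna,
    signature_genes = sig_gene,
    target_map = true_edges,
    enriched_sets = c(component1 = "PATHWAY_C1", component2 = "PATHWAY_C2"),
    pathway_genes = list(component1 = path1, component2 = path2),
    db_rates = data.frame(database = db_names, tpr = tpr, fpr = fpr,
                          stringsAsFactors = FALSE),
    class_assignment = stats::setNames(as.character(lab), samp),
    low_detect_mirnas = mir_ids[low_idx]
  ), class = "SyntheticTruth")

  structure(list(
    mirna = expression_matrix(X, det),
    gene = expression_matrix(Z),
    labels = class_labels(samp, lab, levels = c("long", "short")),
    gene_sets = gsc,
    db_edges = db_edges,
    truth = truth,
    params = list(n_class0 = n_class0, n_class1 = n_class1,
                  p_mirna = p_mirna, q_gene = q_gene,
                  effect_size = effect_size,
                  repression_slope = repression_slope, noise_sd = noise_sd,
                  tpr = tpr, fpr = fpr, seed = seed)
  ), class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf(paste0("SyntheticCohort: %d samples, %d miRNAs, %d genes, ",
                     "%d planted edges\n"),
              nrow(x$mirna$values), ncol(x$mirna$values),
              ncol(x$gene$values), nrow(x$truth$target_map)))
  invisible(x)
}

#' Tabulate the planted truth of a synthetic cohort
#'
#' Flattens a `SyntheticTruth` into a long machine-readable table
#' (`section`, `id`, `partner`, `value`) suitable for test assertions and
#' TSV round-trips.
#'
#' @param truth `SyntheticTruth` object.
#' @return data frame with one row per planted fact.
#' @export
truth_report <- function(truth) {
  if (!inherits(truth, "SyntheticTruth")) stop("expected a SyntheticTruth")
  section <- function(name, id, partner = "", value = NA_real_) {
    n <- length(id)
    data.frame(section = rep(name, n), id = as.character(id),
               partner = rep_len(as.character(partner), n),
               value = rep_len(value, n), stringsAsFactors = FALSE)
  }
  rows <- list(
    section("component1_mirna", truth$component1_mirnas),
    section("component2_mirna", truth$component2_mirnas),
    section("target_edge", truth$target_map$mirna,
            truth$target_map$gene, truth$target_map$slope),
    section("enriched_set", truth$enriched_sets,
            names(truth$enriched_sets)),
    section("class", names(truth$class_assignment),
            truth$class_assignment)
  )
  out <- do.call(rbind, rows[vapply(rows, nrow, 1L) > 0])
  rownames(out) <- NULL
  out
}

#' @rdname truth_report
#' @param report data frame from `truth_report()`.
#' @param path file path.
#' @export
write_truth_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname truth_report
#' @export
read_truth_report <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "character",
                                   "numeric"))
}
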