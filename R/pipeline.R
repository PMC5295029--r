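#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with the
#' analysis defaults this pipeline reproduces: 10% detection filter, FDR
#' 0.15 and |log2 FC| > 1 for differential expression, GSEA FDR 0.05,
#' correlation-circle inner radius 0.3, 2-of-3 target-prediction
#' consensus, network q < 0.1, and 10x10 repeated cross-validation for
#' the signature SVM. The two tuning grids (sPLS-DA keepX, rCCA
#' penalties) default to coarse desk-scale grids; widen them via the
#' config for exhaustive tuning.
#'
#' @param synthetic include a default synthetic-cohort block (`TRUE`) or
#'   an empty `inputs` block to fill with file paths (`FALSE`).
#' @param seed global seed; per-stage seeds are derived as
#'   `(seed * 1000 + stage_index) mod (2^31 - 1)`.
#' @return nested configuration list.
#' @export
default_config <- function(synthetic = TRUE, seed = 1) {
  cfg <- list(
    seed = seed,
    output_dir = NULL,
    detection = list(min_fraction = 0.10),
    diffexp = list(max_q = 0.15, min_abs_log2fc = 1, n_perm = 200),
    splsda = list(ncomp = 2, keepX = NULL, max_ncomp = 2,
                  keepX_grid = c(1, 5, 10, 25, 50), folds = 10),
    splsda_gene = list(ncomp = 2, keepX = c(100, 100), max_ncomp = 2,
                       keepX_grid = c(25, 50, 100, 200), folds = 10),
    gsea = list(n_perm = 200, weight_exponent = 1, min_size = 10,
                max_size = 500, fdr_threshold = 0.05),
    rcca = list(lambda1 = NULL, lambda2 = NULL, grid_points = 8,
                folds = 5, use_selected = TRUE, inner_radius = 0.3,
                dimensions = NULL),
    network = list(variance_fraction = 0.75, min_support = 2,
                   max_q = 0.1),
    stsvm = list(a = 2, steps = 2, n_perm = 300, alpha = 0.05,
                 repeats = 10, folds = 10, nested_selection = FALSE)
  )
  if (synthetic) {
    cfg$synthetic <- list(n_class0 = 14, n_class1 = 26, p_mirna = 614,
                          q_gene = 2000, effect_size = 2,
                          repression_slope = 1, noise_sd = 0.5)
  } else {
    cfg$inputs <- list(mirna = NULL, gene = NULL, labels = NULL,
                       gene_sets = NULL, target_dbs = NULL)
  }
  cfg
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# fill defaults and enforce the exactly-one-input-source invariant
validate_config <- function(config) {
  if (is.null(config$seed)) stop("config error [E_CONFIG]: `seed` is mandatory")
  has_inp <- !is.null(config$inputs)
  has_syn <- !is.null(config$synthetic)
  if (has_inp == has_syn) {
    stop("config error [E_CONFIG]: exactly one of `inputs` and ",
         "`synthetic` must be present")
  }
  base <- default_config(synthetic = has_syn, seed = config$seed)
  modifyList(base, config)
}

stage_seed <- function(seed, k) (as.double(seed) * 1000 + k) %% 2147483647

#' Run the full integrative pipeline
#'
#' Executes, in order: detection filter, miRNA sPLS-DA (tuned if no keepX
#' given), miRNA differential expression with global permutation test,
#' per-component trait GSEA on the gene matrix, gene sPLS-DA, rCCA of the
#' selected submatrices (penalties tuned if not given), correlation
#' circle and CIM, top-variance anticorrelation x database-consensus
#' network with hub statistics, and stSVM signature selection with
#' repeated cross-validated SVM evaluation. Any stage failure aborts with
#' the stage name and an `[E_<STAGE>]` code.
#'
#' @param config list from [default_config()]/[read_config()]; validated
#'   on entry.
#' @return report list with every stage's inputs, parameters and outputs;
#'   if `config$output_dir` is set the report bundle is also written via
#'   [write_report()].
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  seed <- config$seed
  report <- list(config = config)

  wrap <- function(stage, code, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed [%s]: %s", stage, code,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- input ----------------------------------------------------------
  data <- wrap("input", "E_INPUT", {
    if (!is.null(config$synthetic)) {
      do.call(generate_cohort,
              c(config$synthetic, list(seed = stage_seed(seed, 1))))
    } else {
      inp <- config$inputs
      dbs <- lapply(inp$target_dbs, read_edge_list)
      list(mirna = read_expression(inp$mirna),
           gene = read_expression(inp$gene),
           labels = read_labels(inp$labels),
           gene_sets = read_gmt(inp$gene_sets),
           db_edges = dbs, truth = NULL)
    }
  })
  report$truth <- data$truth

  mirna <- wrap("detection_filter", "E_FILTER", {
    if (!is.null(data$mirna$detected)) {
      detection_filter(data$mirna, config$detection$min_fraction)
    } else data$mirna
  })
  report$n_mirna_after_filter <- ncol(mirna$values)
  gene <- data$gene
  labels <- data$labels

  # --- miRNA sPLS-DA --------------------------------------------------
  report$splsda_mirna <- wrap("splsda_mirna", "E_SPLSDA", {
    run_splsda_stage(mirna, labels, config$splsda, stage_seed(seed, 2))
  })

  # --- differential expression ---------------------------------------
  report$diffexp <- wrap("diffexp", "E_DIFFEXP", {
    tab <- random_variance_ttest(mirna, labels)
    sel <- fold_change_filter(tab, config$diffexp$min_abs_log2fc,
                              config$diffexp$max_q)
    glob <- global_permutation_test(mirna, labels,
                                    n_perm = config$diffexp$n_perm,
                                    fdr_threshold = config$diffexp$max_q,
                                    seed = stage_seed(seed, 3))
    list(table = tab, selected = sel, global = glob)
  })

  # --- trait GSEA per component --------------------------------------
  report$gsea <- wrap("gsea_trait", "E_GSEA", {
    g <- config$gsea
    lapply(seq_len(min(2, report$splsda_mirna$model$ncomp)), function(h) {
      gsea_phenotype_permutation(
        gene, report$splsda_mirna$model$x_scores[, h], data$gene_sets,
        n_perm = g$n_perm, weight_exponent = g$weight_exponent,
        min_size = g$min_size, max_size = g$max_size,
        seed = stage_seed(seed, 10 + h), fdr_threshold = g$fdr_threshold)
    })
  })

  # --- gene sPLS-DA ---------------------------------------------------
  report$splsda_gene <- wrap("splsda_gene", "E_SPLSDA_GENE", {
    run_splsda_stage(gene, labels, config$splsda_gene, stage_seed(seed, 4))
  })

  # --- rCCA -----------------------------------------------------------
  report$rcca <- wrap("rcca", "E_RCCA", {
    r <- config$rcca
    Xr <- if (isTRUE(r$use_selected)) {
      sel <- unique(unlist(lapply(
        seq_len(report$splsda_mirna$model$ncomp),
        function(h) selected_features(report$splsda_mirna$model, h))))
      mirna$values[, sel, drop = FALSE]
    } else mirna$values
    Zr <- if (isTRUE(r$use_selected)) {
      sel <- unique(unlist(lapply(
        seq_len(report$splsda_gene$model$ncomp),
        function(h) selected_features(report$splsda_gene$model, h))))
      gene$values[, sel, drop = FALSE]
    } else gene$values
    if (is.null(r$lambda1) || is.null(r$lambda2)) {
      np <- r$grid_points
      tun <- tune_rcca(
        Xr, Zr,
        grid1 = seq(0.001, 0.05, length.out = np + 2)[2:(np + 1)],
        grid2 = seq(0.0001, 0.05, length.out = np + 2)[2:(np + 1)],
        folds = r$folds, seed = stage_seed(seed, 5))
      r$lambda1 <- tun$lambda1; r$lambda2 <- tun$lambda2
    } else tun <- NULL
    model <- fit_rcca(Xr, Zr, r$lambda1, r$lambda2)
    d <- if (length(model$canonical_correlations) >= 2) {
      select_dimensions(model$canonical_correlations,
                        override = r$dimensions)
    } else 1L
    circle <- correlation_circle(model, Xr, Zr,
                                 inner_radius = r$inner_radius)
    cim <- if (any(circle$block == "mirna") && any(circle$block == "gene"))
      cim_similarity(circle) else NULL
    list(model = model, tuning = tun, lambda1 = r$lambda1,
         lambda2 = r$lambda2, d = d, circle = circle, cim = cim,
         x_features = colnames(Xr), z_features = colnames(Zr))
  })

  # --- integrated network --------------------------------------------
  report$network <- wrap("target_network", "E_NETWORK", {
    nw <- config$network
    circ <- report$rcca$circle
    mir_keep <- circ$feature_id[circ$block == "mirna"]
    gene_keep <- circ$feature_id[circ$block == "gene"]
    if (!length(mir_keep) || !length(gene_keep)) {
      stop("no retained features in one block after the correlation circle")
    }
    # variance rank is taken over the whole gene matrix, then intersected
    # with the rCCA-retained genes
    gene_keep <- intersect(gene_keep,
                           variance_top_fraction(gene$values,
                                                 nw$variance_fraction))
    if (!length(gene_keep)) stop("no gene passes the variance filter")
    anticorr <- pairwise_anticorrelation(
      mirna$values[, mir_keep, drop = FALSE],
      gene$values[, gene_keep, drop = FALSE])
    consensus <- consensus_predictions(data$db_edges, nw$min_support)
    net <- build_integrated_network(anticorr, consensus, nw$max_q)
    hubs <- if (nrow(net$edges)) hub_statistics(net) else NULL
    list(anticorr = anticorr, consensus = consensus, network = net,
         hubs = hubs)
  })

  # --- stSVM signature ------------------------------------------------
  report$signature <- wrap("stsvm", "E_STSVM", {
    s <- config$stsvm
    net <- report$network$network
    if (!nrow(net$edges)) stop("integrated network is empty")
    run_stsvm(mirna, gene, labels, net, a = s$a, steps = s$steps,
              n_perm = s$n_perm, alpha = s$alpha, repeats = s$repeats,
              folds = s$folds, seed = stage_seed(seed, 6),
              nested_selection = isTRUE(s$nested_selection))
  })

  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  class(report) <- "mirmint_report"
  report
}

# shared sPLS-DA stage: tune when keepX not fixed
run_splsda_stage <- function(m, labels, cfg, seed) {
  if (is.null(cfg[["keepX"]])) {
    tun <- tune_splsda(m, labels, max_ncomp = cfg$max_ncomp,
                       keepX_grid = cfg$keepX_grid, folds = cfg$folds,
                       seed = seed)
    ncomp <- max(tun$best_ncomp, min(2, cfg$max_ncomp))
    keepX <- tun$keepX_path[seq_len(ncomp)]
  } else {
    tun <- NULL
    ncomp <- cfg$ncomp
    keepX <- cfg[["keepX"]]
  }
  model <- fit_splsda(m, labels, ncomp = ncomp, keepX = keepX)
  list(model = model, tuning = tun, ncomp = ncomp, keepX = keepX,
       selected = lapply(seq_len(ncomp), function(h)
         selected_features(model, h)))
}

#' @export
print.mirmint_report <- function(x, ...) {
  cat("mirmint pipeline report\n")
  cat(sprintf("  miRNAs after filter: %d\n", x$n_mirna_after_filter))
  cat(sprintf("  sPLS-DA: %d comps, keepX %s\n", x$splsda_mirna$ncomp,
              paste(x$splsda_mirna$keepX, collapse = "/")))
  cat(sprintf("  DE miRNAs: %d (FC-filtered %d)\n",
              sum(x$diffexp$table$q <= x$config$diffexp$max_q),
              length(x$diffexp$selected$features)))
  cat(sprintf("  network: %d miRNAs, %d genes, %d edges\n",
              length(x$network$network$mirnas),
              length(x$network$network$genes),
              nrow(x$network$network$edges)))
  cat(sprintf("  signature: %d features, CV AUC %.3f\n",
              length(x$signature$selected), x$signature$cv$auc_mean))
  invisible(x)
}

#' Write the report bundle to a directory
#'
#' Emits TSV tables (component memberships, differential expression,
#' enrichment, circle points, network edges, hubs, signature, ROC), a
#' GraphML export of the integrated network, the configuration echo
#' (YAML) and a JSON run manifest. Output is byte-identical across runs
#' with the same config and seed.
#'
#' @param report list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  comp <- do.call(rbind, lapply(
    seq_len(report$splsda_mirna$model$ncomp), function(h) {
      ids <- selected_features(report$splsda_mirna$model, h)
      data.frame(component = h, feature_id = ids,
                 loading = report$splsda_mirna$model$x_weights[ids, h],
                 stringsAsFactors = FALSE)
    }))
  w(comp, "splsda_mirna_components.tsv")
  w(report$diffexp$table, "diffexp_mirna.tsv")
  w(data.frame(feature_id = report$diffexp$selected$features,
               direction = as.character(report$diffexp$selected$direction),
               stringsAsFactors = FALSE), "diffexp_selected.tsv")
  for (h in seq_along(report$gsea)) {
    w(report$gsea[[h]], sprintf("gsea_component%d.tsv", h))
  }
  w(data.frame(dimension = seq_along(
      report$rcca$model$canonical_correlations),
      correlation = report$rcca$model$canonical_correlations),
    "rcca_correlations.tsv")
  w(report$rcca$circle, "circle_points.tsv")
  w(report$network$network$edges, "network_edges.tsv")
  if (!is.null(report$network$hubs)) {
    w(report$network$hubs$degrees, "network_degrees.tsv")
  }
  write_network_graphml(report$network$network,
                        file.path(dir, "network.graphml"))
  w(data.frame(feature_id = report$signature$selected,
               p = report$signature$p[report$signature$selected],
               score = report$signature$score[report$signature$selected]),
    "signature.tsv")
  w(report$signature$cv$roc, "roc.tsv")
  w(data.frame(repeat_id = seq_along(report$signature$cv$auc_per_repeat),
               auc = report$signature$cv$auc_per_repeat), "auc.tsv")
  write_config(report$config, file.path(dir, "config_echo.yaml"))

  manifest <- list(
    package = "mirmint",
    seed = report$config$seed,
    n_mirna_after_filter = report$n_mirna_after_filter,
    splsda_keepX = report$splsda_mirna$keepX,
    n_de = sum(report$diffexp$table$q <= report$config$diffexp$max_q),
    n_de_fc = length(report$diffexp$selected$features),
    global_p = report$diffexp$global$p_value,
    lambda1 = report$rcca$lambda1, lambda2 = report$rcca$lambda2,
    rcca_d = report$rcca$d,
    n_network_mirna = length(report$network$network$mirnas),
    n_network_gene = length(report$network$network$genes),
    n_network_edges = nrow(report$network$network$edges),
    signature = report$signature$selected,
    auc_mean = report$signature$cv$auc_mean,
    auc_sd = report$signature$cv$auc_sd)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Export an integrated network to GraphML
#' @param net `IntegratedNetwork`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  nodes <- data.frame(
    name = c(net$mirnas, net$genes),
    block = c(rep("mirna", length(net$mirnas)),
              rep("gene", length(net$genes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    net$edges[, c("mirna", "gene", "r", "q", "db_support")],
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Rank-sum comparison of signature features between sample groups
#'
#' Two-sided Wilcoxon rank-sum test per feature between two groups, with
#' BH correction and the direction of the shift — the generic utility for
#' checking a signature's behavior in an independent grouping.
#'
#' @param expr [expression_matrix()] or samples x features matrix.
#' @param groups [class_labels()] or two-level factor over the samples.
#' @param features feature ids to test (must exist in `expr`).
#' @return data frame: `feature_id`, `median_group0`, `median_group1`,
#'   `direction` (`up_group0`/`up_group1`), `p`, `q`.
#' @export
compare_signature_groups <- function(expr, groups, features) {
  X <- get_values(expr)
  lab <- if (inherits(groups, "ClassLabels")) align_labels(expr, groups)
         else factor(groups)
  if (nlevels(lab) != 2) stop("groups must have exactly two levels")
  if (any(table(lab) < 2)) stop("each group needs >= 2 samples")
  missing <- setdiff(features, colnames(X))
  if (length(missing)) {
    stop("feature(s) absent: ", paste(missing, collapse = ", "))
  }
  res <- lapply(features, function(f) {
    v0 <- X[lab == levels(lab)[1], f]
    v1 <- X[lab == levels(lab)[2], f]
    p <- suppressWarnings(stats::wilcox.test(v0, v1)$p.value)
    data.frame(feature_id = f,
               median_group0 = stats::median(v0),
               median_group1 = stats::median(v1),
               direction = ifelse(stats::median(v0) >= stats::median(v1),
                                  "up_group0", "up_group1"),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Command-line entry point
#'
#' Thin dispatcher used by `inst/cli/mirmint.R`:
#' `mirmint simulate <config.yaml> <outdir>` writes a synthetic cohort's
#' input files; `mirmint run <config.yaml>` runs the pipeline (the config
#' must set `output_dir`). Exit codes: 2 validation error, 1 computation
#' error, 0 success.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code (invisibly).
#' @export
mirmint_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: mirmint.R {simulate <config.yaml> <outdir> | run <config.yaml>}"
  if (length(args) < 2) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  code <- tryCatch({
    if (cmd == "simulate") {
      if (length(args) < 3) stop("[E_CONFIG] simulate needs an outdir")
      cfg <- validate_config(yaml::read_yaml(args[2]))
      if (is.null(cfg$synthetic)) stop("[E_CONFIG] config has no synthetic block")
      co <- do.call(generate_cohort,
                    c(cfg$synthetic, list(seed = stage_seed(cfg$seed, 1))))
      dir.create(args[3], showWarnings = FALSE, recursive = TRUE)
      write_expression(co$mirna, file.path(args[3], "mirna.tsv"))
      write_expression(co$gene, file.path(args[3], "gene.tsv"))
      write_labels(co$labels, file.path(args[3], "labels.tsv"))
      write_gmt(co$gene_sets, file.path(args[3], "gene_sets.gmt"))
      for (d in co$db_edges) {
        write_edge_list(d, file.path(args[3], paste0(d$database_name, ".tsv")))
      }
      write_truth_report(truth_report(co$truth),
                         file.path(args[3], "truth.tsv"))
      0L
    } else if (cmd == "run") {
      cfg <- read_config(args[2])
      if (is.null(cfg$output_dir)) stop("[E_CONFIG] config must set output_dir")
      run_pipeline(cfg)
      0L
    } else {
      message(usage); 2L
    }
  }, error = function(e) {
    message(conditionMessage(e))
    if (grepl("E_CONFIG", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
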