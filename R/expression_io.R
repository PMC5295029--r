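#' Expression matrix container
#'
#' A light container for a samples x features matrix of log2-scale
#' expression values with optional per-cell detection flags (as provided,
#' e.g., by array feature-extraction software). Sample and feature
#' identifiers are carried as dimnames and must be unique.
#'
#' @param values numeric matrix, samples in rows, features in columns, with
#'   unique non-empty rownames (sample ids) and colnames (feature ids). All
#'   values must be finite.
#' @param detected optional logical matrix of the same shape and dimnames,
#'   `TRUE` where the feature was called detected in that sample.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and (possibly `NULL`) `detected`.
#' @export
expression_matrix <- function(values, detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (sample ids) and colnames (feature ids)")
  }
  dup_s <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(unique(dup_s), collapse = ", "))
  }
  dup_f <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_f)) {
    stop("duplicated feature id(s): ", paste(unique(dup_f), collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stop("`values` contains non-finite entries")
  }
  if (!is.null(detected)) {
    if (!is.matrix(detected) || !is.logical(detected)) {
      stop("`detected` must be a logical matrix")
    }
    if (!identical(dim(detected), dim(values))) {
      stop("`detected` must have the same shape as `values`")
    }
    dimnames(detected) <- dimnames(values)
  }
  structure(list(values = values, detected = detected),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d samples x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detected)) "" else " (with detection flags)"))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to query.
#' @export
sample_ids <- function(x) rownames(get_values(x))

#' @rdname expression_matrix
#' @export
feature_ids <- function(x) colnames(get_values(x))

# Accept either an ExpressionMatrix or a bare samples x features matrix.
get_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an ExpressionMatrix or a numeric matrix")
}

#' Per-sample binary class labels
#'
#' @param ids character vector of sample ids.
#' @param label vector (character or factor) of class labels; exactly two
#'   distinct classes, both non-empty. The first factor level is treated as
#'   class0 throughout (e.g. `long`), the second as class1 (e.g. `short`).
#' @param levels optional explicit level order.
#' @return `ClassLabels` object: list with `sample_ids` and factor `label`.
#' @export
class_labels <- function(ids, label, levels = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated sample ids in labels")
  if (length(ids) != length(label)) stop("ids and labels differ in length")
  f <- if (is.null(levels)) factor(as.character(label)) else
    factor(as.character(label), levels = levels)
  if (nlevels(f) != 2) stop("labels must contain exactly two classes, got: ",
                            paste(levels(f), collapse = ", "))
  if (any(table(f) == 0) || anyNA(f)) stop("both classes must be non-empty")
  structure(list(sample_ids = ids, label = f), class = "ClassLabels")
}

#' @export
print.ClassLabels <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("ClassLabels: %d samples (%s)\n", length(x$sample_ids),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Return the label factor aligned to the sample order of an expression matrix.
align_labels <- function(m, y) {
  ids <- sample_ids(m)
  if (!setequal(ids, y$sample_ids) || length(ids) != length(y$sample_ids)) {
    stop("label sample ids do not match the expression matrix exactly")
  }
  y$label[match(ids, y$sample_ids)]
}

#' Read an expression matrix from a tab-separated file
#'
#' The file has one header line and one id column; `orientation` says
#' whether data rows are features (the common array export layout) or
#' samples. The returned matrix is always samples x features.
#'
#' @param path file path.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @return [expression_matrix()] object (without detection flags).
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows",
                                            "samples_in_rows")) {
  orientation <- match.arg(orientation)
  parsed <- parse_tsv_matrix(path)
  m <- parsed$values
  if (orientation == "features_in_rows") m <- t(m)
  expression_matrix(m)
}

# Shared strict TSV matrix parser: first row = header ids, first column =
# row ids. Errors name the offending row/column.
parse_tsv_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  col_ids <- header[-1]
  if (anyDuplicated(col_ids)) {
    stop("duplicated id(s) in header: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  }
  nfld <- length(header)
  row_ids <- character(length(fields) - 1)
  vals <- matrix(NA_real_, nrow = length(fields) - 1, ncol = length(col_ids))
  for (i in seq_along(row_ids)) {
    f <- fields[[i + 1]]
    if (length(f) != nfld) {
      stop(sprintf("ragged row %d (id '%s'): %d fields, expected %d",
                   i + 1, f[1], length(f), nfld))
    }
    row_ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    bad <- which(is.na(v) & f[-1] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in row '%s', column '%s'",
                   f[-1][bad[1]], f[1], col_ids[bad[1]]))
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicated row id(s): ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  rownames(vals) <- row_ids
  colnames(vals) <- col_ids
  list(values = vals)
}

#' Write an expression matrix to a tab-separated file
#'
#' @param m [expression_matrix()] object or samples x features matrix.
#' @param path output path.
#' @param orientation layout of the written file; see [read_expression()].
#' @param id_header label for the id column header cell.
#' @export
write_expression <- function(m, path,
                             orientation = c("features_in_rows",
                                             "samples_in_rows"),
                             id_header = "feature_id") {
  orientation <- match.arg(orientation)
  v <- get_values(m)
  if (orientation == "features_in_rows") v <- t(v)
  lines <- c(paste(c(id_header, colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i) {
               paste(c(rownames(v)[i],
                       format(v[i, ], digits = 17, trim = TRUE,
                              scientific = FALSE)), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Filter features by detection rate
#'
#' Keeps feature j iff it was called detected in at least
#' `ceiling(min_fraction * n)` samples, so a feature detected in exactly the
#' minimum fraction of samples passes (e.g. 4 of 40 at 10%). Feature order
#' is preserved; the operation is idempotent.
#'
#' @param m [expression_matrix()] with detection flags.
#' @param min_fraction minimum detection proportion, in (0, 1].
#' @return filtered `ExpressionMatrix` (flags subset alongside values).
#' @export
detection_filter <- function(m, min_fraction = 0.10) {
  if (!inherits(m, "ExpressionMatrix")) stop("`m` must be an ExpressionMatrix")
  if (is.null(m$detected)) {
    stop("no detection flags present: supply `detected` when constructing ",
         "the matrix, or skip detection filtering")
  }
  if (!is.numeric(min_fraction) || length(min_fraction) != 1 ||
      min_fraction <= 0 || min_fraction > 1) {
    stop("`min_fraction` must be a single proportion in (0, 1]")
  }
  n <- nrow(m$values)
  need <- ceiling(min_fraction * n)
  keep <- colSums(m$detected) >= need
  expression_matrix(m$values[, keep, drop = FALSE],
                    m$detected[, keep, drop = FALSE])
}

#' Read and write two-column sample label files
#'
#' Plain TSV with header `sample_id<TAB>label`.
#' @param path file path.
#' @param levels optional class level order (first level = class0).
#' @export
read_labels <- function(path, levels = NULL) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (ncol(d) < 2) stop("label file must have two columns: sample_id, label")
  class_labels(d[[1]], d[[2]], levels = levels)
}

#' @rdname read_labels
#' @param y `ClassLabels` object.
#' @export
write_labels <- function(y, path) {
  writeLines(c("sample_id\tlabel",
               paste(y$sample_ids, as.character(y$label), sep = "\t")), path)
  invisible(path)
}

#' Gene-set collection (GMT dialect)
#'
#' @param sets named list of character vectors of member feature ids.
#' @param description character vector of per-set descriptions (recycled
#'   from "" when missing).
#' @return `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a named list")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicated set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  if (any(lengths(sets) == 0)) {
    stop("empty set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  if (is.null(description)) description <- rep("", length(sets))
  description <- rep_len(as.character(description), length(sets))
  names(description) <- names(sets)
  structure(list(sets = sets, description = description),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Lines with fewer than three fields are rejected with their line number.
#'
#' @param path file path.
#' @return [gene_set_collection()] object.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param gsc `GeneSetCollection` object.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$description[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' miRNA-to-gene target prediction edge set
#'
#' @param database_name short database label.
#' @param mirna,gene character vectors (parallel) of directed edges.
#' @return `TargetPredictionSet` object with an `edges` data frame.
#' @export
target_prediction_set <- function(database_name, mirna, gene) {
  edges <- data.frame(mirna = as.character(mirna), gene = as.character(gene),
                      stringsAsFactors = FALSE)
  key <- paste(edges$mirna, edges$gene, sep = "\r")
  if (anyDuplicated(key)) {
    d <- edges[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate edge in database '%s': %s -> %s",
                 database_name, d$mirna, d$gene))
  }
  structure(list(database_name = database_name, edges = edges),
            class = "TargetPredictionSet")
}

#' Read and write two-column miRNA-to-gene edge lists
#'
#' TSV with header `mirna<TAB>gene`, one predicted interaction per row.
#' @param path file path.
#' @param database_name label stored on the returned set.
#' @export
read_edge_list <- function(path, database_name = basename(path)) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character")
  if (ncol(d) < 2) stop("edge list must have two columns: mirna, gene")
  target_prediction_set(database_name, d[[1]], d[[2]])
}

#' @rdname read_edge_list
#' @param tps `TargetPredictionSet` object.
#' @export
write_edge_list <- function(tps, path) {
  writeLines(c("mirna\tgene",
               paste(tps$edges$mirna, tps$edges$gene, sep = "\t")), path)
  invisible(path)
}
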