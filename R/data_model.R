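#' Single-cell perturbation dataset
#'
#' A light container for log-transformed single-cell expression with one
#' perturbation condition label per cell. Values are assumed to be already
#' log-transformed, as in the distributed Perturb-seq datasets; use
#' `normalize = TRUE` in [read_dataset()] to opt in to size-factor
#' normalization plus `log1p` on raw counts.
#'
#' @param expression Numeric matrix, cells in rows, genes in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per column.
#' @param cell_labels Character vector of condition labels, one per cell
#'   (any dialect accepted by [parse_condition_label()]).
#' @param sep,control Label dialect, see [parse_condition_label()].
#'
#' @return An object of class `perturb_dataset` with elements `expression`
#'   (genes in colnames), `gene_ids` and `cell_labels` (canonicalized).
#' @export
perturb_dataset <- function(expression, gene_ids, cell_labels,
                            sep = "+", control = "ctrl") {
  expression <- as.matrix(expression)
  stopifnot(is.numeric(expression),
            length(gene_ids) == ncol(expression),
            length(cell_labels) == nrow(expression))
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (!all(is.finite(expression))) stop("expression values must be finite")
  cell_labels <- canonicalize_labels(cell_labels, sep, control)
  if (!any(cell_labels == control)) {
    stop("dataset has no control ('", control, "') cells", call. = FALSE)
  }
  colnames(expression) <- gene_ids
  structure(
    list(expression = expression, gene_ids = as.character(gene_ids),
         cell_labels = cell_labels, control = control, sep = sep),
    class = "perturb_dataset"
  )
}

#' @export
print.perturb_dataset <- function(x, ...) {
  type <- label_type(unique(x$cell_labels), x$sep, x$control)
  cat("perturb_dataset: ", nrow(x$expression), " cells x ",
      length(x$gene_ids), " genes\n", sep = "")
  cat("  conditions: ", sum(type == "single"), " single, ",
      sum(type == "double"), " double, plus control\n", sep = "")
  invisible(x)
}

#' Pseudobulk expression matrix
#'
#' The central container for condition-level data: a genes x conditions
#' matrix of mean log-expression with a designated control column. Columns
#' are named by canonical condition labels and rows by gene identifiers.
#'
#' @param values Numeric matrix, genes in rows, conditions in columns.
#'   `dimnames` supply gene identifiers and condition labels unless given
#'   explicitly.
#' @param gene_ids,condition_labels Optional explicit dimnames.
#' @param sep,control Label dialect, see [parse_condition_label()].
#'
#' @return An object of class `pseudobulk_matrix` (a numeric matrix with
#'   attributes `control` and `sep`).
#' @export
pseudobulk_matrix <- function(values, gene_ids = rownames(values),
                              condition_labels = colnames(values),
                              sep = "+", control = "ctrl") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), !is.null(gene_ids), !is.null(condition_labels))
  if (ncol(values) < 2L) stop("pseudobulk matrix needs at least 2 conditions")
  if (anyDuplicated(gene_ids)) stop("gene identifiers must be unique")
  if (!all(is.finite(values))) stop("pseudobulk values must be finite")
  condition_labels <- canonicalize_labels(condition_labels, sep, control)
  if (anyDuplicated(condition_labels)) {
    stop("condition labels must be unique after canonicalization")
  }
  if (sum(condition_labels == control) != 1L) {
    stop("exactly one control ('", control, "') column required", call. = FALSE)
  }
  dimnames(values) <- list(as.character(gene_ids), condition_labels)
  structure(values, control = control, sep = sep,
            class = c("pseudobulk_matrix", class(values)))
}

is_pseudobulk <- function(x) inherits(x, "pseudobulk_matrix")

#' @export
print.pseudobulk_matrix <- function(x, ...) {
  type <- label_type(colnames(x), pb_sep(x), pb_control(x))
  cat("pseudobulk_matrix: ", nrow(x), " genes x ", ncol(x), " conditions (",
      sum(type == "single"), " single, ", sum(type == "double"),
      " double, control '", pb_control(x), "')\n", sep = "")
  invisible(x)
}

pb_control <- function(pb) attr(pb, "control")
pb_sep <- function(pb) attr(pb, "sep")

#' @rdname pseudobulk_matrix
#' @param pb A `pseudobulk_matrix`.
#' @export
control_profile <- function(pb) {
  stopifnot(is_pseudobulk(pb))
  pb[, pb_control(pb)]
}

#' @rdname pseudobulk_matrix
#' @export
condition_labels <- function(pb) colnames(pb)

#' @rdname pseudobulk_matrix
#' @export
gene_ids <- function(pb) rownames(pb)

#' Subset a pseudobulk matrix by condition or gene
#'
#' Identifier-based subsetting that preserves the `pseudobulk_matrix` class
#' and control designation. `subset_conditions()` keeps the control column
#' by default (most downstream operations require it); `subset_genes()`
#' reorders rows to the given identifiers.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param labels Canonical condition labels to keep.
#' @param keep_control Keep the control column even if not listed (default
#'   `TRUE`).
#' @return A [pseudobulk_matrix()].
#' @export
subset_conditions <- function(pb, labels, keep_control = TRUE) {
  stopifnot(is_pseudobulk(pb))
  labels <- unique(labels)
  if (keep_control && !(pb_control(pb) %in% labels)) {
    labels <- c(pb_control(pb), labels)
  }
  missing <- setdiff(labels, colnames(pb))
  if (length(missing) > 0L) {
    stop("conditions not present in pseudobulk: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pseudobulk_matrix(unclass(pb)[, labels, drop = FALSE],
                    sep = pb_sep(pb), control = pb_control(pb))
}

#' @rdname subset_conditions
#' @param genes Gene identifiers to keep (in order).
#' @export
subset_genes <- function(pb, genes) {
  stopifnot(is_pseudobulk(pb))
  missing <- setdiff(genes, rownames(pb))
  if (length(missing) > 0L) {
    stop("genes not present in pseudobulk: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  pseudobulk_matrix(unclass(pb)[genes, , drop = FALSE],
                    sep = pb_sep(pb), control = pb_control(pb))
}

#' Aggregate a single-cell dataset to condition pseudobulk
#'
#' Each output column is the arithmetic mean of the log-expression of the
#' cells carrying that condition label. The result is invariant to the order
#' of cells within a condition.
#'
#' @param dataset A [perturb_dataset()].
#' @return A [pseudobulk_matrix()] (genes x conditions).
#' @export
pseudobulk <- function(dataset) {
  stopifnot(inherits(dataset, "perturb_dataset"))
  labels <- dataset$cell_labels
  conditions <- unique(labels)
  vals <- vapply(conditions, function(cond) {
    colMeans(dataset$expression[labels == cond, , drop = FALSE])
  }, numeric(length(dataset$gene_ids)))
  rownames(vals) <- dataset$gene_ids
  pseudobulk_matrix(vals, sep = dataset$sep, control = dataset$control)
}

#' Select the most highly expressed genes in the control condition
#'
#' Returns the `n` genes with the highest control-column value. Ties are
#' broken by smaller row index, so the selection is deterministic and stable
#' under the dataset's gene order. If `n` exceeds the gene count, all genes
#' are returned in ranked order.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param n Number of genes to select (default 1000, the conventional
#'   read-out gene set size).
#' @return Character vector of gene identifiers, ranked by control expression.
#' @export
top_expressed_genes <- function(pb, n = 1000L) {
  stopifnot(is_pseudobulk(pb), n >= 1L)
  ctrl <- control_profile(pb)
  ord <- order(-ctrl, seq_along(ctrl))
  rownames(pb)[ord[seq_len(min(n, nrow(pb)))]]
}

#' Read a perturbation dataset from disk
#'
#' Two on-disk formats are supported:
#' \describe{
#'   \item{`"pseudobulk-table"`}{UTF-8 tab-separated table, first column gene
#'     identifiers, remaining columns canonical condition labels with the
#'     control column named by `control`. Returns a [pseudobulk_matrix()].}
#'   \item{`"h5ad"`}{An AnnData container. Read through the `anndata` Python
#'     package (invoked via `python` on the PATH); the expression matrix is
#'     taken from `X` or a named `layer`, condition labels from the per-cell
#'     metadata column `condition_field`, gene identifiers from the variable
#'     axis. Returns a [perturb_dataset()].}
#' }
#'
#' @param path File path.
#' @param format `"pseudobulk-table"` or `"h5ad"` (default guessed from the
#'   file extension).
#' @param condition_field Name of the per-cell metadata column holding the
#'   condition labels (h5ad only; default `"condition"`).
#' @param layer Optional layer name for h5ad expression (default: `X`).
#' @param normalize If `TRUE`, apply size-factor normalization (to the median
#'   total count) followed by `log1p` to the values, for raw-count inputs.
#'   Never applied silently.
#' @param sep,control Label dialect.
#' @return A [perturb_dataset()] or [pseudobulk_matrix()].
#' @export
read_dataset <- function(path, format = c("auto", "pseudobulk-table", "h5ad"),
                         condition_field = "condition", layer = NULL,
                         normalize = FALSE, sep = "+", control = "ctrl") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.h5ad$", path)) "h5ad" else "pseudobulk-table"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "pseudobulk-table") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L) stop("pseudobulk table needs >= 2 condition columns")
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- tab[[1]]
    if (normalize) vals <- log1p(normalize_columns(expm1(vals)))
    if (!any(canonicalize_labels(colnames(vals), sep, control) == control)) {
      stop("no control ('", control, "') column in ", path, call. = FALSE)
    }
    pseudobulk_matrix(vals, sep = sep, control = control)
  } else {
    read_h5ad_dataset(path, condition_field = condition_field, layer = layer,
                      normalize = normalize, sep = sep, control = control)
  }
}

# Median-total size-factor normalization of a genes x conditions count matrix.
normalize_columns <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("non-positive column total during normalization")
  sweep(counts, 2, totals / stats::median(totals), "/")
}

# Bridge to the anndata Python package: export matrix, genes and labels as
# temporary TSV files and read them back. Dense export; intended for the
# pseudobulk-scale and fixture-scale inputs this package handles in R.
read_h5ad_dataset <- function(path, condition_field = "condition",
                              layer = NULL, normalize = FALSE,
                              sep = "+", control = "ctrl") {
  python <- Sys.which("python")
  if (!nzchar(python)) stop("h5ad input requires 'python' on the PATH")
  out_dir <- tempfile("h5ad_export_")
  dir.create(out_dir)
  on.exit(unlink(out_dir, recursive = TRUE), add = TRUE)
  script <- file.path(out_dir, "export.py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import anndata as ad",
    "path, field, layer, out = sys.argv[1:5]",
    "adata = ad.read_h5ad(path)",
    "if field not in adata.obs.columns:",
    "    sys.exit(f'missing condition column: {field}')",
    "X = adata.X if layer == '' else adata.layers[layer]",
    "X = np.asarray(X.todense()) if hasattr(X, 'todense') else np.asarray(X)",
    "np.savetxt(out + '/X.tsv', X, delimiter='\\t')",
    "with open(out + '/genes.txt', 'w') as fh:",
    "    fh.write('\\n'.join(map(str, adata.var_names)) + '\\n')",
    "with open(out + '/labels.txt', 'w') as fh:",
    "    fh.write('\\n'.join(map(str, adata.obs[field])) + '\\n')"
  ), script)
  status <- system2(python, c(shQuote(script), shQuote(path),
                              shQuote(condition_field),
                              shQuote(if (is.null(layer)) "" else layer),
                              shQuote(out_dir)),
                    stdout = FALSE, stderr = file.path(out_dir, "err.txt"))
  if (status != 0L) {
    err <- tryCatch(readLines(file.path(out_dir, "err.txt")),
                    error = function(e) character())
    stop("h5ad import failed: ", paste(err, collapse = " "), call. = FALSE)
  }
  X <- as.matrix(utils::read.table(file.path(out_dir, "X.tsv"), sep = "\t"))
  genes <- readLines(file.path(out_dir, "genes.txt"))
  labels <- readLines(file.path(out_dir, "labels.txt"))
  if (normalize) {
    X <- t(log1p(normalize_columns(t(X))))
  }
  perturb_dataset(X, gene_ids = genes, cell_labels = labels,
                  sep = sep, control = control)
}

#' Write a pseudobulk matrix to the tabular interchange format
#'
#' Writes the UTF-8 tab-separated format read back by [read_dataset()]:
#' first column `gene`, remaining columns canonical condition labels.
#'
#' @param pb A [pseudobulk_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pseudobulk <- function(pb, path) {
  stopifnot(is_pseudobulk(pb))
  tab <- data.frame(gene = rownames(pb), unclass(pb), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
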