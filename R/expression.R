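#' Construct a cell-type x gene expression table
#'
#' Values are nonnegative per-cell-type expression summaries ("adjusted tpm"
#' in the source single-cell atlases: the average expression of a gene in an
#' annotated cell type). The two atlas flavors are conventionally labelled
#' `"lineage"` (lineage annotations up to terminal divisions) and
#' `"terminal"` (terminal cell types across time windows); they are always
#' analyzed separately, never merged.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   cell types in columns (colnames = cell-type ids).
#' @param dataset_label Dataset label string (e.g. `"lineage"`, `"terminal"`).
#' @return An `expression_table` object.
#' @export
expression_table <- function(values, dataset_label) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) == 0) stop("expression table has no cell types")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and cell-type colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene_id in expression table")
  if (anyDuplicated(colnames(values))) stop("duplicate cell_type in expression table")
  if (anyNA(values)) stop("expression table contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at (", rownames(values)[bad[1]], ", ",
         colnames(values)[bad[2]], ")")
  }
  structure(list(values = values, dataset_label = as.character(dataset_label)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table '%s': %d genes x %d cell types\n",
              x$dataset_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Load a cell-type x gene expression table from TSV
#'
#' Long layout expects columns `gene_id`, `cell_type`, `value`; (gene, cell
#' type) combinations absent from the file are taken as 0, and a duplicated
#' combination is an error naming the key. Wide layout expects a `gene_id`
#' first column and one column per cell type. `.gz` files are read
#' transparently.
#'
#' @param path TSV path.
#' @param layout `"long"` or `"wide"`.
#' @param dataset_label Dataset label stored on the result.
#' @return An [expression_table()].
#' @export
load_expression_table <- function(path, layout = c("long", "wide"),
                                  dataset_label) {
  layout <- match.arg(layout)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    need <- c("gene_id", "cell_type", "value")
    if (!all(need %in% names(df))) {
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    }
    key_dup <- duplicated(df[, c("gene_id", "cell_type")])
    if (any(key_dup)) {
      k <- df[which(key_dup)[1], ]
      stop("duplicate expression entry for (", k$gene_id, ", ", k$cell_type, ")")
    }
    if (!is.numeric(df$value)) stop("expression values must be numeric")
    genes <- sort(unique(df$gene_id))
    cells <- sort(unique(df$cell_type))
    m <- matrix(0, nrow = length(genes), ncol = length(cells),
                dimnames = list(genes, cells))
    m[cbind(match(df$gene_id, genes), match(df$cell_type, cells))] <- df$value
  } else {
    if (names(df)[1] != "gene_id") stop("wide layout requires first column 'gene_id'")
    if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in wide table")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    if (!is.numeric(m)) stop("expression values must be numeric")
  }
  expression_table(m, dataset_label = dataset_label)
}

#' Write an expression table to long-format TSV
#'
#' Emits every (gene, cell type) entry including zeros, so a reload
#' reproduces the table exactly.
#'
#' @param table An [expression_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(table, path) {
  m <- table$values
  long <- data.frame(
    gene_id = rep(rownames(m), times = ncol(m)),
    cell_type = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  long <- long[order(long$gene_id, long$cell_type, method = "radix"), ]
  .write_tsv(long, path)
}

#' Binarize an expression table into expressed-cell-type sets
#'
#' A gene is called expressed in a cell type when its value is strictly
#' greater than `threshold` (the atlas convention: expressed iff adjusted tpm
#' is higher than 0). Genes absent from the table are defined as expressed
#' nowhere, so annotation-derived pairs with unprofiled genes flow through and
#' receive a coefficient of 0 via the zero-denominator rule.
#'
#' @param table An [expression_table()].
#' @param threshold Nonnegative binarization cutoff (default 0, strict).
#' @return An `expressed_sets` object: logical membership matrix (genes x
#'   cell types), the cell-type `universe`, the `threshold` used, and the
#'   table's `dataset_label`.
#' @export
binarize <- function(table, threshold = 0) {
  stopifnot(inherits(table, "expression_table"),
            length(threshold) == 1, threshold >= 0)
  structure(list(
    membership = table$values > threshold,
    universe = colnames(table$values),
    threshold = threshold,
    dataset_label = table$dataset_label
  ), class = "expressed_sets")
}

#' @export
print.expressed_sets <- function(x, ...) {
  cat(sprintf("expressed_sets '%s': %d genes over %d cell types (threshold > %g)\n",
              x$dataset_label, nrow(x$membership), length(x$universe),
              x$threshold))
  invisible(x)
}

#' Cell types in which a gene is expressed
#'
#' @param sets An [binarize()] result.
#' @param gene_id Gene identifier; a gene absent from the underlying table
#'   yields an empty set.
#' @return Character vector of cell-type ids.
#' @export
expressed_in <- function(sets, gene_id) {
  stopifnot(inherits(sets, "expressed_sets"), length(gene_id) == 1)
  i <- match(gene_id, rownames(sets$membership))
  if (is.na(i)) return(character())
  sets$universe[sets$membership[i, ]]
}
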