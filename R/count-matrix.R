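#' Construct a labeled count matrix
#'
#' The central container for expression data: a non-negative integer matrix
#' of genes (rows) by columns (cells of a single-cell reference, or bulk
#' samples), with unique gene and column identifiers and an optional
#' per-column cell-type label.
#'
#' @param values Non-negative numeric matrix (base or [Matrix::Matrix]),
#'   genes in rows, cells/samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param column_ids Character vector of unique column identifiers.
#' @param labels Optional character vector of per-column cell-type labels.
#' @return An object of class `count_matrix`: a list with elements
#'   `values`, `gene_ids`, `column_ids`, `labels`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         column_ids = colnames(values), labels = NULL) {
  gene_ids <- as.character(gene_ids)
  column_ids <- as.character(column_ids)
  assert_that(nrow(values) == length(gene_ids),
              "number of rows must equal length of gene_ids")
  assert_that(ncol(values) == length(column_ids),
              "number of columns must equal length of column_ids")
  assert_that(!anyDuplicated(gene_ids), "duplicate gene_ids")
  assert_that(anyDuplicated(column_ids) == 0 || ncol(values) == 0,
              "duplicate column_ids")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    assert_that(length(labels) == length(column_ids),
                "labels must have one entry per column")
  }
  if (length(values) > 0) {
    assert_that(min(values) >= 0, "counts must be non-negative")
  }
  dimnames(values) <- list(gene_ids, column_ids)
  structure(
    list(values = values, gene_ids = gene_ids, column_ids = column_ids,
         labels = labels),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d columns%s\n",
              length(x$gene_ids), length(x$column_ids),
              if (is.null(x$labels)) "" else
                sprintf(" (%d labeled types)", length(unique(x$labels)))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

# Column subset preserving labels.
subset_columns <- function(x, idx) {
  count_matrix(x$values[, idx, drop = FALSE],
               gene_ids = x$gene_ids,
               column_ids = x$column_ids[idx],
               labels = if (is.null(x$labels)) NULL else x$labels[idx])
}

as_dense <- function(x) {
  m <- as.matrix(x$values)
  dimnames(m) <- list(x$gene_ids, x$column_ids)
  m
}
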