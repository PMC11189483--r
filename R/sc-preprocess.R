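#' Read a count matrix from disk
#'
#' Supports the 10X-style triplet layout written by [write_reference()]
#' (`matrix.mtx` + `barcodes.tsv` + `features.tsv`, gene IDs in the first
#' column of the feature file) and a dense TSV with a header row of column
#' IDs and gene IDs in the first column.
#'
#' @param path Directory (triplet) or file (dense TSV).
#' @param format `"tenx_triplet"` or `"dense_tsv"`.
#' @param labels_path Optional two-column TSV (barcode TAB cell type);
#'   defaults to `labels.tsv` inside a triplet directory when present.
#' @return A [count_matrix()], labeled when labels are available. Input
#'   gene order is preserved.
#' @export
read_counts <- function(path, format = c("tenx_triplet", "dense_tsv"),
                        labels_path = NULL) {
  format <- match.arg(format)
  if (format == "tenx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    assert_that(file.exists(mtx), paste0("missing ", mtx))
    values <- Matrix::readMM(mtx)
    barcodes <- readLines(file.path(path, "barcodes.tsv"))
    features <- read.table(file.path(path, "features.tsv"), sep = "\t",
                           header = FALSE, colClasses = "character")
    if (ncol(values) != length(barcodes)) {
      stop("matrix has ", ncol(values), " columns but barcode file has ",
           length(barcodes), " entries", call. = FALSE)
    }
    if (nrow(values) != nrow(features)) {
      stop("matrix has ", nrow(values), " rows but feature file has ",
           nrow(features), " entries", call. = FALSE)
    }
    gene_ids <- features[[1]]
    if (is.null(labels_path)) {
      cand <- file.path(path, "labels.tsv")
      if (file.exists(cand)) labels_path <- cand
    }
  } else {
    tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      row.names = NULL, colClasses = NA)
    gene_ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
    barcodes <- colnames(values)
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    if (length(readLines(labels_path)) == 0) {
      return(count_matrix(values, gene_ids = gene_ids,
                          column_ids = barcodes,
                          labels = if (length(barcodes) == 0) character(0)))
    }
    lab <- read.table(labels_path, sep = "\t", header = FALSE,
                      colClasses = "character")
    map <- setNames(lab[[2]], lab[[1]])
    missing <- setdiff(barcodes, names(map))
    assert_that(length(missing) == 0,
                paste0("labels missing for: ",
                       paste(head(missing, 5), collapse = ", ")))
    labels <- unname(map[barcodes])
  }
  count_matrix(values, gene_ids = gene_ids, column_ids = barcodes,
               labels = labels)
}

#' Per-column quality-control metrics
#'
#' For each column computes `n_genes_by_counts` (genes with a positive
#' count), `total_counts` (sum over genes), and `pct_counts_mito`
#' (percentage of total counts from mitochondrial genes). Mitochondrial
#' membership is decided by a case-insensitive gene-ID prefix, or an
#' explicit gene set.
#'
#' @param matrix A [count_matrix()].
#' @param mito_prefix Gene-ID prefix marking mitochondrial genes.
#' @param mito_genes Optional explicit mitochondrial gene set, overriding
#'   the prefix rule.
#' @return A tibble with one row per column: `column_id`,
#'   `n_genes_by_counts`, `total_counts`, `pct_counts_mito`. Columns with
#'   zero total counts get `pct_counts_mito = 0` and are flagged in the
#'   `zero_total` column.
#' @export
compute_qc <- function(matrix, mito_prefix = "MT-", mito_genes = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  assert_that(ncol(matrix$values) > 0, "matrix has no columns")
  v <- matrix$values
  if (is.null(mito_genes)) {
    is_mito <- startsWith(toupper(matrix$gene_ids), toupper(mito_prefix))
  } else {
    is_mito <- matrix$gene_ids %in% mito_genes
  }
  n_genes <- Matrix::colSums(v > 0)
  total <- Matrix::colSums(v)
  mito_total <- if (any(is_mito)) {
    Matrix::colSums(v[is_mito, , drop = FALSE])
  } else {
    rep(0, ncol(v))
  }
  pct <- ifelse(total > 0, 100 * mito_total / total, 0)
  tibble(
    column_id = matrix$column_ids,
    n_genes_by_counts = as.integer(n_genes),
    total_counts = as.numeric(total),
    pct_counts_mito = as.numeric(pct),
    zero_total = unname(total == 0)
  )
}

#' Filter cells on quality-control thresholds
#'
#' Keeps exactly the columns with `min_genes <= n_genes_by_counts <=
#' max_genes` (inclusive bounds) and `pct_counts_mito < max_mito_pct`
#' (strict). Column order and retained values are untouched; labels are
#' carried along. The operation is idempotent.
#'
#' @param matrix A [count_matrix()].
#' @param qc QC tibble from [compute_qc()] on the same matrix.
#' @param min_genes,max_genes Inclusive bounds on genes with positive
#'   counts (defaults 200 and 3000).
#' @param max_mito_pct Strict upper bound on mitochondrial percentage
#'   (default 5).
#' @return The filtered [count_matrix()]. Removing every cell raises a
#'   warning, not an error.
#' @export
filter_cells <- function(matrix, qc, min_genes = 200, max_genes = 3000,
                         max_mito_pct = 5) {
  stopifnot(inherits(matrix, "count_matrix"))
  assert_that(identical(qc$column_id, matrix$column_ids),
              "qc metrics do not match matrix columns")
  keep <- qc$n_genes_by_counts >= min_genes &
    qc$n_genes_by_counts <= max_genes &
    qc$pct_counts_mito < max_mito_pct
  if (!any(keep)) warning("all cells removed by QC filter", call. = FALSE)
  subset_columns(matrix, which(keep))
}

#' Default fine-to-pooled cell-type maps
#'
#' Two reference maps from fine-grained immune cell types to the six
#' pooled lineages (B cell, CD4 T cell, CD8 T cell, Myeloid, NK cell,
#' Other): `"tenx"` covers the ten FACS-sorted PBMC populations the
#' synthetic generator mimics, and `"whole_blood"` covers the fourteen
#' flow-cytometry types of a whole-blood cohort (plasmablasts pooled with
#' B cells, dendritic cells with the monocytes into Myeloid, basophils
#' into Other — assignments a user can override with their own table).
#'
#' @param reference `"tenx"` or `"whole_blood"`.
#' @return A tibble with columns `fine_type`, `pooled_type`.
#' @export
default_pooling_map <- function(reference = c("tenx", "whole_blood")) {
  reference <- match.arg(reference)
  if (reference == "tenx") {
    tibble(
      fine_type = c("CD19+ B cells", "CD14+ monocytes", "CD34+ cells",
                    "CD4+ helper T cells", "CD4+/CD25+ regulatory T cells",
                    "CD4+/CD45RA+/CD25- naive T cells",
                    "CD4+/CD45RO+ memory T cells", "CD56+ NK cells",
                    "CD8+ cytotoxic T cells", "CD8+/CD45RA+ naive T cells"),
      pooled_type = c("B cell", "Myeloid", "Other",
                      "CD4 T cell", "CD4 T cell", "CD4 T cell",
                      "CD4 T cell", "NK cell", "CD8 T cell", "CD8 T cell")
    )
  } else {
    tibble(
      fine_type = c("B naive", "B Ex", "B NSM", "B SM", "Plasmablasts",
                    "CD4 T cells", "CD8 T cells", "Basophils",
                    "mDCs", "pDCs", "NK cells",
                    "Monocytes C", "Monocytes I", "Monocytes NC"),
      pooled_type = c("B cell", "B cell", "B cell", "B cell", "B cell",
                      "CD4 T cell", "CD8 T cell", "Other",
                      "Myeloid", "Myeloid", "NK cell",
                      "Myeloid", "Myeloid", "Myeloid")
    )
  }
}

pooled_lineages <- function() {
  c("B cell", "CD4 T cell", "CD8 T cell", "Myeloid", "NK cell", "Other")
}

#' Pool fine-grained cell-type labels into lineages
#'
#' Element-wise relabeling of fine cell-type names into the six pooled
#' lineages; preserves length and order.
#'
#' @param labels Character vector of fine-grained labels.
#' @param map A two-column data frame (`fine_type`, `pooled_type`) or a
#'   named character vector. Must cover every observed label and map into
#'   the six pooled lineage names.
#' @return Character vector of pooled labels, same length as `labels`.
#' @export
pool_cell_types <- function(labels, map = default_pooling_map()) {
  if (is.data.frame(map)) {
    lookup <- setNames(map[[2]], map[[1]])
  } else {
    lookup <- map
  }
  bad_values <- setdiff(unique(unname(lookup)), pooled_lineages())
  assert_that(length(bad_values) == 0,
              paste0("pooling map targets unknown lineages: ",
                     paste(bad_values, collapse = ", ")))
  unmapped <- setdiff(unique(labels), names(lookup))
  if (length(unmapped) > 0) {
    stop("unmapped cell-type labels: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  unname(lookup[labels])
}
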