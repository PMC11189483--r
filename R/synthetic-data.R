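#' Configuration for the synthetic single-cell generator
#'
#' Parameters of the generative model used to build labeled synthetic
#' single-cell references: per-type expression signatures with marker genes
#' at a fixed fold-change, negative-binomial counts with independent
#' dropout, per-cell library-size variation, and a designated set of
#' mitochondrial genes (prefixed `MT-`) whose rates can be boosted to make
#' cells that fail the mitochondrial QC filter.
#'
#' @param n_genes Number of genes.
#' @param n_cell_types Number of fine-grained cell types (default 10,
#'   pooling to 6 lineages under [default_pooling_map()]).
#' @param cells_per_type Cells simulated per type.
#' @param nb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param dropout_rate Probability that an expressed count is zeroed
#'   independently (technical dropout), in `[0, 1)`.
#' @param marker_frac Fraction of genes designated markers, split
#'   round-robin across cell types.
#' @param marker_fold Fold-change of a marker's rate in its owning type over
#'   every other type; at least 2.
#' @param mito_frac Fraction of genes designated mitochondrial.
#' @param mito_boost Multiplier on mitochondrial gene rates (1 = none);
#'   raising it makes high-mito cells for QC fixtures.
#' @param depth_range Length-2 numeric, min/max per-cell library-size
#'   multiplier (uniform).
#' @param seed Integer seed; all generator outputs are pure functions of
#'   the configuration including this seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000, n_cell_types = 10,
                             cells_per_type = 300, nb_dispersion = 2,
                             dropout_rate = 0.2, marker_frac = 0.3,
                             marker_fold = 5, mito_frac = 0.02,
                             mito_boost = 1, depth_range = c(0.5, 2),
                             seed = 1L) {
  assert_that(n_cell_types >= 2, "n_cell_types must be at least 2")
  assert_that(cells_per_type >= 1, "cells_per_type must be at least 1")
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  assert_that(nb_dispersion > 0, "nb_dispersion must be positive")
  assert_that(marker_frac >= 0 && marker_frac <= 1,
              "marker_frac must be in [0, 1]")
  assert_that(marker_frac == 0 || marker_fold >= 2,
              "marker_fold must be at least 2")
  assert_that(length(depth_range) == 2 && depth_range[1] > 0 &&
                depth_range[2] >= depth_range[1],
              "depth_range must be an increasing positive pair")
  n_markers <- round(marker_frac * n_genes)
  n_mito <- round(mito_frac * n_genes)
  if (n_markers > 0 && n_markers < n_cell_types) {
    stop("n_genes too small: ", n_markers, " marker genes cannot cover ",
         n_cell_types, " cell types", call. = FALSE)
  }
  if (n_markers + n_mito > n_genes) {
    stop("n_genes too small to host ", n_markers, " markers and ",
         n_mito, " mitochondrial genes", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes),
         n_cell_types = as.integer(n_cell_types),
         cells_per_type = as.integer(cells_per_type),
         nb_dispersion = nb_dispersion, dropout_rate = dropout_rate,
         marker_frac = marker_frac, marker_fold = marker_fold,
         mito_frac = mito_frac, mito_boost = mito_boost,
         depth_range = depth_range, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Fine-grained type names mirroring a FACS-sorted PBMC panel, so the
# shipped default pooling map applies to simulated references out of the box.
reference_type_names <- function(n) {
  base <- c("CD19+ B cells", "CD14+ monocytes", "CD34+ cells",
            "CD4+ helper T cells", "CD4+/CD25+ regulatory T cells",
            "CD4+/CD45RA+/CD25- naive T cells", "CD4+/CD45RO+ memory T cells",
            "CD56+ NK cells", "CD8+ cytotoxic T cells",
            "CD8+/CD45RA+ naive T cells")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, paste0("synthetic type ", seq_len(n - length(base))))
}

#' Generate per-type expression signatures
#'
#' Draws per-gene baseline expression rates from a long-tailed (log-normal)
#' distribution, assigns marker genes round-robin across cell types with a
#' guaranteed fold-change in the owning type, and flags a subset of genes as
#' mitochondrial (IDs prefixed `MT-`).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `signature_set` with elements `genes`,
#'   `cell_types`, `mean_rates` (types x genes matrix), `marker_assignment`
#'   (named character, `NA` for non-markers) and `mito_genes`.
#' @export
generate_signatures <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n_mito <- round(config$mito_frac * config$n_genes)
    n_markers <- round(config$marker_frac * config$n_genes)
    n_plain <- config$n_genes - n_mito
    genes <- c(sprintf("MT-%03d", seq_len(n_mito)),
               sprintf("GENE%04d", seq_len(n_plain)))
    mito_genes <- genes[seq_len(n_mito)]
    types <- reference_type_names(config$n_cell_types)

    base <- rlnorm_rates(config$n_genes)
    rates <- matrix(rep(base, each = config$n_cell_types),
                    nrow = config$n_cell_types,
                    dimnames = list(types, genes))
    # markers drawn from non-mito genes, dealt round-robin over types
    marker_assignment <- setNames(rep(NA_character_, config$n_genes), genes)
    if (n_markers > 0) {
      non_mito <- setdiff(genes, mito_genes)
      marker_genes <- sample(non_mito, n_markers)
      owners <- types[((seq_len(n_markers) - 1L) %% config$n_cell_types) + 1L]
      marker_assignment[marker_genes] <- owners
      for (i in seq_len(n_markers)) {
        rates[owners[i], marker_genes[i]] <-
          rates[owners[i], marker_genes[i]] * config$marker_fold
      }
    }
    if (n_mito > 0 && config$mito_boost != 1) {
      rates[, mito_genes] <- rates[, mito_genes] * config$mito_boost
    }
    structure(
      list(genes = genes, cell_types = types, mean_rates = rates,
           marker_assignment = marker_assignment, mito_genes = mito_genes),
      class = "signature_set"
    )
  })
}

# Long-tailed positive baseline rates; scaled so a 1000-gene cell at unit
# depth has a few thousand total counts, desk-scale for 10X-like data.
rlnorm_rates <- function(n) stats::rlnorm(n, meanlog = 0.5, sdlog = 1.2)

#' Simulate labeled single cells from a signature set
#'
#' Each cell of type `t` draws, per gene `g`, a negative-binomial count with
#' mean `depth * rate[t, g]` (depth uniform in `depth_range`) and the
#' configured dispersion, then zeroes each count independently with
#' probability `dropout_rate`.
#'
#' @param sig A `signature_set` from [generate_signatures()].
#' @param config The matching [synthetic_config()].
#' @return A labeled [count_matrix()] with `n_genes` rows and
#'   `n_cell_types * cells_per_type` columns.
#' @export
simulate_cells <- function(sig, config) {
  stopifnot(inherits(sig, "signature_set"),
            inherits(config, "synthetic_config"))
  assert_that(length(sig$genes) == config$n_genes &&
                length(sig$cell_types) == config$n_cell_types,
              "signature set inconsistent with config")
  with_seed(derive_seed(config$seed, 1L), {
    g <- config$n_genes
    blocks <- lapply(seq_along(sig$cell_types), function(ti) {
      n_cells <- config$cells_per_type
      depth <- runif(n_cells, config$depth_range[1], config$depth_range[2])
      mu <- outer(sig$mean_rates[ti, ], depth)            # g x n_cells
      counts <- matrix(rnbinom(g * n_cells, size = config$nb_dispersion,
                               mu = as.vector(mu)), nrow = g)
      if (config$dropout_rate > 0) {
        keep <- matrix(rbinom(g * n_cells, 1L, 1 - config$dropout_rate),
                       nrow = g)
        counts <- counts * keep
      }
      counts
    })
    values <- do.call(cbind, blocks)
    labels <- rep(sig$cell_types, each = config$cells_per_type)
    barcodes <- sprintf("CELL-%05d", seq_len(ncol(values)))
    count_matrix(Matrix::Matrix(values, sparse = TRUE),
                 gene_ids = sig$genes, column_ids = barcodes,
                 labels = labels)
  })
}

#' Write a labeled reference as a 10X-style triplet
#'
#' Emits `matrix.mtx` (sparse matrix-market), `barcodes.tsv`,
#' `features.tsv` (gene ID in column 1) and `labels.tsv`
#' (barcode TAB cell type). Round-trips losslessly through
#' [read_counts()] with `format = "tenx_triplet"`.
#'
#' @param matrix A labeled [count_matrix()].
#' @param directory Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_reference <- function(matrix, directory) {
  stopifnot(inherits(matrix, "count_matrix"))
  assert_that(!is.null(matrix$labels), "reference must be labeled")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(matrix$values, sparse = TRUE)
  Matrix::writeMM(methods::as(m, "CsparseMatrix"),
                  file.path(directory, "matrix.mtx"))
  writeLines(matrix$column_ids, file.path(directory, "barcodes.tsv"))
  write.table(
    data.frame(id = matrix$gene_ids, name = matrix$gene_ids,
               type = "Gene Expression"),
    file.path(directory, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(
    data.frame(barcode = matrix$column_ids, cell_type = matrix$labels),
    file.path(directory, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(directory)
}

#' Write an immune-related gene list
#'
#' Produces a plain-text, one-symbol-per-line gene list containing every
#' marker gene of the signature set plus a configurable fraction of the
#' non-marker genes — the synthetic stand-in for a curated list of
#' immunologically related genes used as a feature-selection criterion.
#'
#' @param sig A `signature_set`.
#' @param path Output file path.
#' @param nonmarker_frac Fraction of non-marker genes to include.
#' @param seed Seed for the non-marker subsample.
#' @return The gene list, invisibly.
#' @export
make_immune_gene_list <- function(sig, path, nonmarker_frac = 0.5,
                                  seed = 1L) {
  stopifnot(inherits(sig, "signature_set"))
  markers <- names(sig$marker_assignment)[!is.na(sig$marker_assignment)]
  non_markers <- setdiff(sig$genes, markers)
  extra <- with_seed(seed, {
    n_extra <- round(nonmarker_frac * length(non_markers))
    if (n_extra > 0) sample(non_markers, n_extra) else character(0)
  })
  genes <- sig$genes[sig$genes %in% c(markers, extra)]  # keep input order
  writeLines(genes, path)
  invisible(genes)
}
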