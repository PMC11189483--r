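test_that("dense TSV matrices parse with shapes and IDs intact", {
  m <- matrix(c(1L, 0L, 3L, 2L, 5L, 0L), nrow = 3,
              dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(m), m), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  cm <- read_counts(path, format = "dense_tsv")
  expect_equal(dim(cm), c(3L, 2L))
  expect_identical(cm$gene_ids, c("GA", "GB", "GC"))
  expect_identical(cm$column_ids, c("s1", "s2"))
  expect_equal(as.matrix(cm$values), m, ignore_attr = TRUE)
})

test_that("inconsistent triplet files are rejected", {
  cells <- small_reference()$cells
  dir <- withr::local_tempdir()
  write_reference(cells, dir)
  # drop one barcode -> count mismatch with the matrix
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  writeLines(barcodes[-1], file.path(dir, "barcodes.tsv"))
  expect_error(read_counts(dir, format = "tenx_triplet"), "barcode")
})

test_that("duplicate identifiers are rejected by the container", {
  expect_error(
    count_matrix(matrix(0L, 2, 1), gene_ids = c("A", "A"),
                 column_ids = "c1"),
    "duplicate")
})

test_that("QC metrics match hand arithmetic on a tiny fixture", {
  # column 1: counts (5, 0, 3) with gene 1 mitochondrial
  m <- toy_counts(matrix(c(5L, 0L, 3L,
                           0L, 0L, 0L), nrow = 3),
                  genes = c("MT-1", "GA", "GB"))
  qc <- compute_qc(m)
  expect_equal(qc$n_genes_by_counts, c(2L, 0L))
  expect_equal(qc$total_counts, c(8, 0))
  expect_equal(qc$pct_counts_mito, c(62.5, 0))
  expect_equal(qc$zero_total, c(FALSE, TRUE))
})

test_that("QC without mitochondrial genes reports zero percentages", {
  m <- toy_counts(matrix(1:6, nrow = 3), genes = c("GA", "GB", "GC"))
  qc <- compute_qc(m)
  expect_equal(qc$pct_counts_mito, c(0, 0))
  # explicit mito set overrides the prefix rule
  qc2 <- compute_qc(m, mito_genes = "GA")
  expect_equal(qc2$pct_counts_mito, 100 * c(1 / 6, 4 / 15))
})

test_that("cell filtering applies inclusive gene bounds and a strict mito bound", {
  # 4 cells sitting exactly on the decision boundaries
  genes <- c("MT-1", sprintf("G%03d", 1:299))
  build_cell <- function(n_pos, mito_pct) {
    counts <- numeric(300)
    # non-mito positive genes get 1 count each; mito gene carries the rest
    non_mito_pos <- n_pos - (mito_pct > 0)
    counts[1 + seq_len(non_mito_pos)] <- 1
    if (mito_pct > 0) {
      counts[1] <- mito_pct / (100 - mito_pct) * non_mito_pos
    }
    counts
  }
  vals <- cbind(build_cell(200, 4.9),   # keep
                build_cell(199, 0),     # too few genes
                build_cell(201, 5.0),   # mito at the strict bound
                build_cell(250, 0))     # keep
  m <- toy_counts(vals, genes = genes)
  qc <- compute_qc(m)
  expect_equal(qc$n_genes_by_counts, c(200L, 199L, 201L, 250L))
  expect_equal(qc$pct_counts_mito[3], 5.0, tolerance = 1e-12)
  kept <- filter_cells(m, qc, min_genes = 200, max_genes = 3000,
                       max_mito_pct = 5)
  expect_identical(kept$column_ids, m$column_ids[c(1, 4)])
})

test_that("filtering matches a brute-force per-cell re-check and is idempotent", {
  # 12 cells engineered so 4 fail each rule disjointly
  cfg <- synthetic_config(n_genes = 400, n_cell_types = 2,
                          cells_per_type = 30, mito_frac = 0.05,
                          mito_boost = 4, dropout_rate = 0.5, seed = 88L)
  cells <- simulate_cells(generate_signatures(cfg), cfg)
  qc <- compute_qc(cells)
  min_g <- as.integer(quantile(qc$n_genes_by_counts, 0.25))
  max_g <- as.integer(quantile(qc$n_genes_by_counts, 0.85))
  max_m <- quantile(qc$pct_counts_mito, 0.7)
  kept <- filter_cells(cells, qc, min_g, max_g, max_m)

  v <- as.matrix(cells$values)
  is_mito <- startsWith(cells$gene_ids, "MT-")
  keep_brute <- vapply(seq_len(ncol(v)), function(j) {
    ng <- sum(v[, j] > 0)
    tot <- sum(v[, j])
    pm <- if (tot > 0) 100 * sum(v[is_mito, j]) / tot else 0
    ng >= min_g && ng <= max_g && pm < max_m
  }, logical(1))
  expect_identical(kept$column_ids, cells$column_ids[keep_brute])
  expect_gt(ncol(kept$values), 0)
  expect_lt(ncol(kept$values), ncol(cells$values))

  # pure column selection, idempotent
  expect_equal(as.matrix(kept$values),
               as.matrix(cells$values)[, keep_brute], ignore_attr = TRUE)
  qc2 <- compute_qc(kept)
  again <- filter_cells(kept, qc2, min_g, max_g, max_m)
  expect_identical(again$column_ids, kept$column_ids)
})

test_that("permissive thresholds keep everything; strict ones warn on empty", {
  cells <- small_reference()$cells
  qc <- compute_qc(cells)
  all_kept <- filter_cells(cells, qc, min_genes = 0, max_genes = Inf,
                           max_mito_pct = 100)
  expect_identical(all_kept$column_ids, cells$column_ids)
  expect_warning(filter_cells(cells, qc, min_genes = 1e9), "all cells")
})

test_that("the reference pooling map sends fine types to their lineages", {
  expect_equal(pool_cell_types("CD4+/CD45RO+ memory T cells"), "CD4 T cell")
  expect_equal(pool_cell_types("CD56+ NK cells"), "NK cell")
  expect_equal(pool_cell_types("CD14+ monocytes"), "Myeloid")
  expect_equal(pool_cell_types("CD34+ cells"), "Other")
  labels <- c("CD19+ B cells", "CD8+ cytotoxic T cells",
              "CD8+/CD45RA+ naive T cells")
  expect_equal(pool_cell_types(labels),
               c("B cell", "CD8 T cell", "CD8 T cell"))
})

test_that("pooling preserves order, supports identity maps, rejects gaps", {
  labels <- c("B cell", "NK cell", "B cell")
  identity_map <- setNames(c("B cell", "NK cell"), c("B cell", "NK cell"))
  expect_identical(pool_cell_types(labels, identity_map), labels)
  expect_error(pool_cell_types(c("B cell", "mystery cells"), identity_map),
               "mystery cells")
  # 14-type whole-blood map covers its panel and lands in the six lineages
  wb <- default_pooling_map("whole_blood")
  expect_equal(nrow(wb), 14)
  pooled <- pool_cell_types(wb$fine_type, wb)
  expect_true(all(pooled %in% c("B cell", "CD4 T cell", "CD8 T cell",
                                "Myeloid", "NK cell", "Other")))
})
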