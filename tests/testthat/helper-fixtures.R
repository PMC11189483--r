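# Shared fixtures, generated in code at test time.

# Small labeled reference: 10 fine types pooled to 6 lineages.
small_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(n_genes = 300, n_cell_types = 10,
                              cells_per_type = 40, marker_fold = 5,
                              dropout_rate = 0.2, seed = 424L)
      sig <- generate_signatures(cfg)
      fine <- simulate_cells(sig, cfg)
      cells <- fine
      cells$labels <- pool_cell_types(cells$labels)
      cache <<- list(config = cfg, sig = sig, fine = fine, cells = cells)
    }
    cache
  }
})

# Hand-built tiny count matrix from an explicit dense matrix.
toy_counts <- function(values, genes = NULL, cols = NULL, labels = NULL) {
  genes <- genes %||% sprintf("G%02d", seq_len(nrow(values)))
  cols <- cols %||% sprintf("c%02d", seq_len(ncol(values)))
  count_matrix(values, gene_ids = genes, column_ids = cols, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A quickly trainable pseudo-bulk train/test pair on the small reference.
small_pseudobulk <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- small_reference()$cells
      tr <- suppressMessages(
        simulate_dataset(ref, 250, C = 120, seed = 31L))
      te <- suppressMessages(
        simulate_dataset(ref, 60, C = 120, seed = 32L))
      cache <<- list(train = tr, test = te)
    }
    cache
  }
})
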