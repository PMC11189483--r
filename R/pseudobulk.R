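#' Split a labeled reference into selection and simulation cells
#'
#' Stratified-by-cell-type partition of the reference columns into a
#' marker/feature-selection part and a mixture-simulation part, so the
#' cells used to pick features never contribute to the pseudo-bulk
#' mixtures (no information leakage). Disjoint and exhaustive;
#' deterministic given the seed.
#'
#' @param matrix A labeled [count_matrix()].
#' @param frac_for_selection Fraction of each type's cells assigned to the
#'   selection part, in (0, 1).
#' @param seed Integer seed.
#' @return A list with `selection` and `simulation` count matrices.
#' @export
split_reference <- function(matrix, frac_for_selection = 0.5, seed = 1L) {
  stopifnot(inherits(matrix, "count_matrix"))
  assert_that(!is.null(matrix$labels), "reference must be labeled")
  assert_that(frac_for_selection > 0 && frac_for_selection < 1,
              "frac_for_selection must be in (0, 1)")
  tab <- table(matrix$labels)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    stop("cannot stratify: cell types with fewer than 2 cells: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    sel_idx <- integer(0)
    for (ty in sort(names(tab))) {
      idx <- which(matrix$labels == ty)
      n_sel <- max(1L, min(length(idx) - 1L,
                           round(frac_for_selection * length(idx))))
      sel_idx <- c(sel_idx, sample(idx, n_sel))
    }
    sel_idx <- sort(sel_idx)
    sim_idx <- setdiff(seq_along(matrix$column_ids), sel_idx)
    list(selection = subset_columns(matrix, sel_idx),
         simulation = subset_columns(matrix, sim_idx))
  })
}

#' Sample ground-truth fraction vectors from a Dirichlet distribution
#'
#' Rows are i.i.d. Dirichlet draws (built from normalized gamma variates),
#' each summing to one — the simulated cell-type composition of one
#' pseudo-bulk sample.
#'
#' @param n_samples Number of samples (rows).
#' @param k Number of cell types (at least 2), or implied by
#'   `cell_type_names`.
#' @param dirichlet_alpha Concentration: scalar (symmetric) or length-`k`
#'   vector; all entries positive. Default 1 = uniform on the simplex.
#' @param seed Integer seed.
#' @param cell_type_names Optional column names.
#' @return A tibble of class `fraction_matrix`: `sample_id` plus one
#'   numeric column per cell type; every row sums to 1.
#' @export
sample_fractions <- function(n_samples, k, dirichlet_alpha = 1, seed = 1L,
                             cell_type_names = NULL) {
  if (!is.null(cell_type_names)) k <- length(cell_type_names)
  assert_that(k >= 2, "need at least 2 cell types")
  assert_that(all(dirichlet_alpha > 0), "dirichlet_alpha must be positive")
  alpha <- rep_len(dirichlet_alpha, k)
  vals <- with_seed(seed, {
    g <- matrix(rgamma(n_samples * k, shape = rep(alpha, each = n_samples)),
                nrow = n_samples)
    g / rowSums(g)
  })
  colnames(vals) <- cell_type_names %||% paste0("type", seq_len(k))
  as_fraction_tbl(vals, sample_ids = sprintf("sample%05d", seq_len(n_samples)))
}

# fraction_matrix tibble helpers ------------------------------------------

as_fraction_tbl <- function(vals, sample_ids) {
  out <- as_tibble(as.data.frame(vals))
  out <- dplyr::bind_cols(tibble(sample_id = sample_ids), out)
  class(out) <- c("fraction_matrix", class(tibble()))
  out
}

#' Convert a fraction tibble to a numeric matrix
#'
#' @param x A `fraction_matrix` tibble (`sample_id` + type columns) or a
#'   numeric matrix (returned as is).
#' @return Numeric samples x types matrix with sample IDs as row names.
#' @export
fraction_values <- function(x) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x))
  m <- as.matrix(x[, setdiff(names(x), "sample_id"), drop = FALSE])
  rownames(m) <- x$sample_id
  m
}

#' Allocate integer cell counts from a fraction vector
#'
#' Largest-remainder rounding of `C * fractions`: floor everything, then
#' hand the leftover cells to the types with the largest fractional parts,
#' ties broken by cell-type order. The result is non-negative and sums to
#' exactly `C`.
#'
#' @param fractions Non-negative numeric vector summing to 1.
#' @param C Total number of cells (default 500).
#' @return Integer vector, same length and names as `fractions`.
#' @export
allocate_cell_counts <- function(fractions, C = 500) {
  assert_that(C >= 1, "C must be at least 1")
  assert_that(all(fractions >= 0) && abs(sum(fractions) - 1) < 1e-6,
              "fractions must be non-negative and sum to 1")
  raw <- C * fractions
  base <- floor(raw)
  leftover <- round(C - sum(base))
  if (leftover > 0) {
    frac_part <- raw - base
    extra <- order(-frac_part, seq_along(fractions))[seq_len(leftover)]
    base[extra] <- base[extra] + 1
  }
  storage.mode(base) <- "integer"
  base
}

#' Mix a pseudo-bulk profile from reference cells
#'
#' For each cell type, samples the requested number of cells uniformly
#' without replacement (falling back to with-replacement, with a message,
#' only when the type's pool is smaller than the request) and sums the
#' selected cells' count vectors feature-wise.
#'
#' @param simulation_cells A labeled [count_matrix()].
#' @param counts_per_type Named integer vector (names = cell types).
#' @param seed Integer seed.
#' @return A list with `profile` (named numeric vector over genes) and
#'   `cells_used` (character vector of selected column IDs).
#' @export
mix_profiles <- function(simulation_cells, counts_per_type, seed = 1L) {
  stopifnot(inherits(simulation_cells, "count_matrix"))
  assert_that(!is.null(simulation_cells$labels), "reference must be labeled")
  wanted <- counts_per_type[counts_per_type > 0]
  absent <- setdiff(names(wanted), unique(simulation_cells$labels))
  if (length(absent) > 0) {
    stop("cell types requested but absent from reference: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    chosen <- integer(0)
    for (ty in names(wanted)) {
      pool <- which(simulation_cells$labels == ty)
      n <- wanted[[ty]]
      if (n > length(pool)) {
        message("pool for '", ty, "' has ", length(pool),
                " cells < requested ", n, "; sampling with replacement")
        chosen <- c(chosen, pool[sample.int(length(pool), n, replace = TRUE)])
      } else {
        chosen <- c(chosen, pool[sample.int(length(pool), n)])
      }
    }
    profile <- Matrix::rowSums(
      simulation_cells$values[, chosen, drop = FALSE])
    names(profile) <- simulation_cells$gene_ids
    list(profile = as.numeric(profile) |> setNames(simulation_cells$gene_ids),
         cells_used = simulation_cells$column_ids[chosen])
  })
}

#' Simulate a pseudo-bulk dataset with known fractions
#'
#' Composes Dirichlet fraction sampling, largest-remainder cell-count
#' allocation (total `C` cells per sample) and cell subsampling/summing
#' into a full pseudo-bulk dataset. The stored ground truth is the
#' continuous Dirichlet draw, not the post-rounding realized proportion.
#'
#' @param reference A labeled [count_matrix()] (labels should already be
#'   pooled to the lineages of interest).
#' @param n_samples Number of pseudo-bulk samples.
#' @param C Cells per sample (default 500).
#' @param dirichlet_alpha Dirichlet concentration (default 1).
#' @param seed Integer seed.
#' @return A list of class `pseudobulk_dataset`: `profiles` (samples x
#'   genes integer matrix), `fractions` (`fraction_matrix` tibble),
#'   `cells_used` (list of character vectors), `config` (echo of the
#'   simulation parameters).
#' @export
simulate_dataset <- function(reference, n_samples, C = 500,
                             dirichlet_alpha = 1, seed = 1L) {
  stopifnot(inherits(reference, "count_matrix"))
  assert_that(!is.null(reference$labels), "reference must be labeled")
  types <- sort(unique(reference$labels))
  if (n_samples == 0) {
    prof <- matrix(0, nrow = 0, ncol = length(reference$gene_ids),
                   dimnames = list(NULL, reference$gene_ids))
    fr <- as_fraction_tbl(
      matrix(numeric(0), 0, length(types),
             dimnames = list(NULL, types)), character(0))
    return(structure(list(profiles = prof, fractions = fr,
                          cells_used = list(),
                          config = list(C = C,
                                        dirichlet_alpha = dirichlet_alpha,
                                        seed = seed)),
                     class = "pseudobulk_dataset"))
  }
  if (length(types) == 1) {
    # degenerate one-type reference: every fraction vector is the one-hot
    fractions <- as_fraction_tbl(
      matrix(1, n_samples, 1, dimnames = list(NULL, types)),
      sample_ids = sprintf("sample%05d", seq_len(n_samples)))
  } else {
    fractions <- sample_fractions(n_samples, k = length(types),
                                  dirichlet_alpha = dirichlet_alpha,
                                  seed = seed, cell_type_names = types)
  }
  fvals <- fraction_values(fractions)
  profiles <- matrix(0, nrow = n_samples, ncol = length(reference$gene_ids),
                     dimnames = list(fractions$sample_id,
                                     reference$gene_ids))
  cells_used <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    counts <- allocate_cell_counts(fvals[i, ], C = C)
    mixed <- mix_profiles(reference, counts,
                          seed = derive_seed(seed, i))
    profiles[i, ] <- mixed$profile
    cells_used[[i]] <- mixed$cells_used
  }
  structure(
    list(profiles = profiles, fractions = fractions,
         cells_used = cells_used,
         config = list(C = C, dirichlet_alpha = dirichlet_alpha,
                       seed = seed)),
    class = "pseudobulk_dataset"
  )
}

#' @export
print.pseudobulk_dataset <- function(x, ...) {
  cat(sprintf("<pseudobulk_dataset> %d samples x %d genes, C = %d\n",
              nrow(x$profiles), ncol(x$profiles), x$config$C))
  invisible(x)
}

#' Write a pseudo-bulk dataset to disk
#'
#' Profiles as a genes x samples TSV, fractions as a samples x types CSV,
#' and a JSON manifest with the simulation config and a digest of the
#' cells used.
#'
#' @param dataset A `pseudobulk_dataset`.
#' @param directory Output directory.
#' @return The directory, invisibly.
#' @export
write_pseudobulk <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  prof <- t(dataset$profiles)                 # genes x samples
  write.table(data.frame(gene_id = rownames(prof), prof,
                         check.names = FALSE),
              file.path(directory, "profiles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$fractions),
                   file.path(directory, "fractions.csv"), row.names = FALSE)
  manifest <- list(config = dataset$config,
                   n_samples = nrow(dataset$profiles),
                   n_genes = ncol(dataset$profiles),
                   cells_used_total = sum(lengths(dataset$cells_used)))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}
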