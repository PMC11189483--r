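#' Read a gene list file
#'
#' One symbol per line; whitespace is stripped, blank lines ignored,
#' duplicates removed (first occurrence kept).
#'
#' @param path Plain-text file.
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  genes <- unique(lines[nzchar(lines)])
  assert_that(length(genes) > 0, paste0("empty gene list: ", path))
  genes
}

#' Rank genes by variance-stabilized variability
#'
#' Scores each gene by the variance of its depth-adjusted Pearson
#' residuals: with `mu_gc = depth_c * p_g` (`depth_c` the cell's total
#' counts, `p_g` the gene's pooled count proportion), the residual is
#' `(x_gc - mu_gc) / sqrt(mu_gc + mu_gc^2 / theta)` under a fixed
#' negative-binomial dispersion `theta`, clipped to `+/- sqrt(n_cells)`.
#' The score is the residual variance across cells — an analytic
#' variance-stabilized highly-variable-gene criterion. Ties are broken
#' lexicographically by gene ID so the ranking is a deterministic total
#' order; zero-count genes score 0 and rank last.
#'
#' @param matrix A [count_matrix()] with at least two columns.
#' @param theta Fixed negative-binomial dispersion (default 100).
#' @param clip Residual clipping bound; default `sqrt(n_cells)`.
#' @return A tibble `gene_id`, `score`, `rank` sorted by rank (1 = most
#'   variable).
#' @export
rank_variable_genes <- function(matrix, theta = 100, clip = NULL) {
  stopifnot(inherits(matrix, "count_matrix"))
  assert_that(ncol(matrix$values) >= 2, "need at least 2 columns")
  x <- as_dense(matrix)
  n_cells <- ncol(x)
  depth <- colSums(x)
  grand <- sum(depth)
  p <- if (grand > 0) rowSums(x) / grand else rep(0, nrow(x))
  clip <- clip %||% sqrt(n_cells)
  mu <- outer(p, depth)                       # genes x cells
  denom <- sqrt(mu + mu^2 / theta)
  resid <- (x - mu) / denom
  resid[!is.finite(resid)] <- 0               # zero-count genes: mu = 0
  resid <- pmin(pmax(resid, -clip), clip)
  score <- apply(resid, 1, var)
  score[p == 0] <- 0
  ord <- order(-score, matrix$gene_ids, method = "radix")
  tibble(gene_id = matrix$gene_ids[ord],
         score = unname(score[ord]),
         rank = seq_along(ord))
}

#' Select the fixed model input feature set
#'
#' Intersects the eligibility criteria first — membership in the immune
#' gene list, presence in every supplied dataset's gene set, and presence
#' in the reference ranking — then takes the top `n_features` eligible
#' genes by variability rank, in rank order. Doing the intersection first
#' guarantees the result has exactly `n_features` genes (or fails loudly).
#'
#' @param ranked Ranking tibble from [rank_variable_genes()].
#' @param immune_set Character vector of immune-related gene symbols.
#' @param dataset_gene_sets List of character vectors, one per additional
#'   dataset the model must be applicable to; may be empty.
#' @param n_features Number of features to select (default 3000).
#' @return An object of class `feature_set`: a tibble `gene_id`, `rank`,
#'   `score` (selection order = rank order) with attribute `n_features`.
#'   Errors with the shortfall if fewer than `n_features` genes are
#'   eligible.
#' @export
select_features <- function(ranked, immune_set, dataset_gene_sets = list(),
                            n_features = 3000) {
  eligible <- ranked$gene_id %in% immune_set
  for (gs in dataset_gene_sets) eligible <- eligible & ranked$gene_id %in% gs
  pool <- ranked[eligible, , drop = FALSE]
  if (nrow(pool) < n_features) {
    stop("only ", nrow(pool), " genes satisfy all criteria; ",
         n_features - nrow(pool), " short of n_features = ", n_features,
         call. = FALSE)
  }
  out <- pool[seq_len(n_features), c("gene_id", "rank", "score")]
  structure(out, class = c("feature_set", class(tibble())),
            n_features = n_features)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes (top by variability rank)\n", nrow(x)))
  NextMethod()
}

feature_genes <- function(fs) {
  if (inherits(fs, "feature_set") || is.data.frame(fs)) fs$gene_id
  else as.character(fs)
}

#' Project a count matrix onto a feature set
#'
#' Reorders rows to the feature-set order; genes absent from the matrix
#' are filled with zero rows (with a warning) so the model input dimension
#' stays fixed across datasets.
#'
#' @param matrix A [count_matrix()].
#' @param fs A `feature_set` (or character vector of gene IDs).
#' @return A [count_matrix()] whose rows are exactly the feature set, in
#'   order.
#' @export
project_to_features <- function(matrix, fs) {
  stopifnot(inherits(matrix, "count_matrix"))
  genes <- feature_genes(fs)
  idx <- match(genes, matrix$gene_ids)
  missing <- genes[is.na(idx)]
  if (length(missing) > 0) {
    warning(length(missing), " feature genes missing from matrix, ",
            "filled with zeros: ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  v <- matrix$values
  out <- Matrix::Matrix(0, nrow = length(genes), ncol = ncol(v),
                        sparse = methods::is(v, "sparseMatrix"))
  present <- !is.na(idx)
  out[present, ] <- v[idx[present], , drop = FALSE]
  count_matrix(out, gene_ids = genes, column_ids = matrix$column_ids,
               labels = matrix$labels)
}

#' Write / read a feature set
#'
#' Serialized as a one-column ordered gene list plus a provenance TSV
#' (`<path>.provenance.tsv`) recording each gene's rank and score.
#'
#' @param fs A `feature_set`.
#' @param path Output path for the gene list.
#' @return `path`, invisibly.
#' @export
write_feature_set <- function(fs, path) {
  writeLines(fs$gene_id, path)
  write.table(as.data.frame(fs), paste0(path, ".provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
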