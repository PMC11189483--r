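#' Normalize a ground-truth fraction table
#'
#' Missing entries (e.g. cell types a flow-cytometry panel did not
#' measure for a sample) are filled with zero, then each sample's row is
#' divided by its total so it sums to one.
#'
#' @param raw A data frame (optionally with a `sample_id` column) or
#'   matrix of non-negative fractions with `NA` for missing entries.
#' @return A `fraction_matrix` tibble. A row that is entirely
#'   zero/missing, or any negative entry, is an error naming the sample.
#' @export
normalize_true_fractions <- function(raw) {
  if (is.data.frame(raw)) {
    ids <- if ("sample_id" %in% names(raw)) raw$sample_id else
      sprintf("sample%05d", seq_len(nrow(raw)))
    m <- as.matrix(raw[, setdiff(names(raw), "sample_id"), drop = FALSE])
  } else {
    m <- as.matrix(raw)
    ids <- rownames(m) %||% sprintf("sample%05d", seq_len(nrow(m)))
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative fraction entries, first at sample ", ids[neg[1, 1]],
         call. = FALSE)
  }
  m[is.na(m)] <- 0
  totals <- rowSums(m)
  if (any(totals == 0)) {
    stop("samples with all-zero fractions: ",
         paste(ids[totals == 0], collapse = ", "), call. = FALSE)
  }
  as_fraction_tbl(m / totals, sample_ids = ids)
}

#' Build a k-fold cross-validation plan
#'
#' Seeded shuffle of the sample indices followed by contiguous chunking
#' into `k` folds whose sizes differ by at most one.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return A list of class `cv_plan`: `n`, `k`, `fold` (per-sample fold
#'   assignment in original sample order), `seed`.
#' @export
make_cv_folds <- function(n, k = 10, seed = 1L) {
  assert_that(n >= k, sprintf("n = %d < k = %d folds", n, k))
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = k, fold = fold, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Cross-validated training and out-of-fold estimation
#'
#' For each fold, trains a fresh model on the complement and predicts the
#' held-out fold; out-of-fold per-quantile estimates are reassembled in
#' the original sample order, so every sample receives exactly one
#' out-of-fold estimate. An evaluation report is computed on the pooled
#' estimates.
#'
#' @param profiles Samples x genes count matrix with gene column names.
#' @param fractions `fraction_matrix` tibble (or matrix) of true
#'   fractions.
#' @param feature_set `feature_set` or gene-ID vector the models use.
#' @param config A [model_config()].
#' @param plan A [make_cv_folds()] plan for `nrow(profiles)` samples.
#' @return A list: `estimates` (samples x types x quantiles array, original
#'   order), `aggregated` (`nnice_estimates` tibble), `report`
#'   (`nnice_report`), `plan`.
#' @export
run_cv <- function(profiles, fractions, feature_set, config, plan) {
  stopifnot(inherits(plan, "cv_plan"))
  fvals <- fraction_values(fractions)
  assert_that(nrow(profiles) == plan$n,
              "plan was made for a different sample count")
  cell_types <- colnames(fvals)
  est <- NULL
  for (f in seq_len(plan$k)) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    fold_config <- config
    fold_config$seed <- derive_seed(config$seed, f)
    model <- build_model(fold_config, cell_types, feature_set)
    model <- train_nnice(model, profiles[train_idx, , drop = FALSE],
                         fvals[train_idx, , drop = FALSE])
    pred <- predict(model, profiles[test_idx, , drop = FALSE])
    if (is.null(est)) {
      est <- array(NA_real_, dim = c(plan$n, dim(pred)[2], dim(pred)[3]),
                   dimnames = c(list(rownames(profiles)), dimnames(pred)[2:3]))
    }
    est[test_idx, , ] <- pred
  }
  aggregated <- aggregate_quantiles(est)
  report <- evaluate_predictions(fvals, est, alpha_mix = config$alpha_mix)
  list(estimates = est, aggregated = aggregated, report = report,
       plan = plan)
}

# Metric triple on one truth/estimate pair; NA-safe for constant truth.
metric_row <- function(y, yhat, alpha_mix) {
  r <- suppressWarnings(pearson_r(y, yhat))
  e <- rmse(y, yhat)
  loss <- if (is.na(r)) NA_real_ else alpha_mix * (1 - r) +
    (1 - alpha_mix) * e
  tibble(r = r, rmse = e, loss = loss, n = length(y))
}

#' Evaluate estimates against true fractions
#'
#' Computes Pearson R, RMSE and the composite loss at three
#' granularities: overall (the quantile-averaged estimates of all cell
#' types concatenated into one pooled vector pair), per cell type
#' (quantile-averaged), per quantile (all types pooled at that quantile),
#' and per (cell type, quantile). A constant truth column makes R (and
#' the composite loss) undefined for that slice; it is reported as
#' missing, not zero.
#'
#' @param true `fraction_matrix` tibble or samples x types matrix of true
#'   fractions (columns must cover the estimated cell types).
#' @param estimates Per-quantile array from [predict.nnice_model()] (or
#'   the `run_cv` pooled array).
#' @param alpha_mix Composite-loss weight, echoed into the report
#'   (default 0.8).
#' @return A tibble of class `nnice_report`: `level` (one of `"overall"`,
#'   `"cell_type"`, `"quantile"`, `"cell_type_x_quantile"`), `cell_type`,
#'   `quantile`, `r`, `rmse`, `loss`, `n`.
#' @export
evaluate_predictions <- function(true, estimates, alpha_mix = 0.8) {
  tvals <- fraction_values(true)
  cell_types <- dimnames(estimates)[[2]]
  qnames <- dimnames(estimates)[[3]]
  missing_types <- setdiff(cell_types, colnames(tvals))
  assert_that(length(missing_types) == 0,
              paste0("truth lacks cell types: ",
                     paste(missing_types, collapse = ", ")))
  assert_that(nrow(tvals) == dim(estimates)[1],
              "truth and estimates disagree on sample count")
  point <- apply(estimates, c(1, 2), mean)
  rows <- list()
  rows[[1]] <- dplyr::bind_cols(
    tibble(level = "overall", cell_type = NA_character_,
           quantile = NA_character_),
    metric_row(as.numeric(tvals[, cell_types]), as.numeric(point),
               alpha_mix))
  for (ct in cell_types) {
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(level = "cell_type", cell_type = ct, quantile = NA_character_),
      metric_row(tvals[, ct], point[, ct], alpha_mix))
  }
  for (qn in qnames) {
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble(level = "quantile", cell_type = NA_character_, quantile = qn),
      metric_row(as.numeric(tvals[, cell_types]),
                 as.numeric(estimates[, , qn]), alpha_mix))
  }
  for (ct in cell_types) {
    for (qn in qnames) {
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(level = "cell_type_x_quantile", cell_type = ct,
               quantile = qn),
        metric_row(tvals[, ct], estimates[, ct, qn], alpha_mix))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha_mix") <- alpha_mix
  class(out) <- c("nnice_report", class(tibble()))
  out
}

#' Write / read an evaluation report
#'
#' Long-format CSV (level, cell_type, quantile, metric, value, n) plus a
#' JSON summary of the overall row; round-trips through
#' [read_report()].
#'
#' @param report An `nnice_report`.
#' @param path CSV output path (the JSON summary lands next to it).
#' @return `path` (write) / an `nnice_report` tibble (read).
#' @export
write_report <- function(report, path) {
  long <- tidyr::pivot_longer(report, cols = c("r", "rmse", "loss"),
                              names_to = "metric", values_to = "value")
  utils::write.csv(as.data.frame(long), path, row.names = FALSE)
  overall <- report[report$level == "overall", ]
  jsonlite::write_json(
    list(alpha_mix = attr(report, "alpha_mix"),
         overall = list(r = overall$r[1], rmse = overall$rmse[1],
                        loss = overall$loss[1], n = overall$n[1])),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(cell_type = "character",
                                         quantile = "character"))
  wide <- tidyr::pivot_wider(long, names_from = "metric",
                             values_from = "value")
  wide <- wide[, c("level", "cell_type", "quantile", "r", "rmse", "loss",
                   "n")]
  out <- as_tibble(wide)
  class(out) <- c("nnice_report", class(tibble()))
  out
}
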