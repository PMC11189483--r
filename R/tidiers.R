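# broom-style tidiers for the fitted model and evaluation report.

#' Tidy a fitted deconvolution model
#'
#' One row per (cell type, quantile) network with its parameter count,
#' epochs run, and final validation metrics.
#'
#' @param x An `nnice_model`.
#' @param ... Unused.
#' @return A tibble: `cell_type`, `quantile`, `n_params`, `epochs_run`,
#'   `val_loss`, `val_r`, `val_rmse` (history columns `NA` before
#'   training).
#' @method tidy nnice_model
#' @export
tidy.nnice_model <- function(x, ...) {
  base <- dplyr::bind_rows(lapply(x$nets, function(net) {
    tibble(cell_type = net$cell_type, quantile = net$q,
           n_params = n_params_net(net))
  }))
  if (is.null(x$history) || nrow(x$history) == 0) {
    return(dplyr::mutate(base, epochs_run = NA_integer_,
                         val_loss = NA_real_, val_r = NA_real_,
                         val_rmse = NA_real_))
  }
  last <- x$history |>
    dplyr::group_by(.data$cell_type, .data$quantile) |>
    dplyr::summarise(epochs_run = max(.data$epoch),
                     val_loss = .data$val_loss[which.max(.data$epoch)],
                     val_r = .data$val_r[which.max(.data$epoch)],
                     val_rmse = .data$val_rmse[which.max(.data$epoch)],
                     .groups = "drop")
  dplyr::left_join(base, last, by = c("cell_type", "quantile"))
}

#' Glance at a fitted deconvolution model
#'
#' @param x An `nnice_model`.
#' @param ... Unused.
#' @return A one-row tibble: `n_nets`, `n_cell_types`, `n_quantiles`,
#'   `n_features`, `hidden_units`, `loss_mode`, `alpha_mix`, `trained`.
#' @method glance nnice_model
#' @export
glance.nnice_model <- function(x, ...) {
  tibble(n_nets = length(x$nets),
         n_cell_types = length(x$cell_types),
         n_quantiles = length(x$config$quantiles),
         n_features = x$config$n_features,
         hidden_units = x$config$hidden_units,
         loss_mode = x$config$loss_mode,
         alpha_mix = x$config$alpha_mix,
         trained = !is.null(x$norm))
}

#' Tidy an evaluation report
#'
#' The report is already a tidy tibble; returned unchanged apart from
#' dropping its class decoration.
#'
#' @param x An `nnice_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy nnice_report
#' @export
tidy.nnice_report <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  attr(out, "alpha_mix") <- NULL
  out
}

#' Glance at an evaluation report
#'
#' @param x An `nnice_report`.
#' @param ... Unused.
#' @return A one-row tibble with the overall pooled `r`, `rmse`, `loss`,
#'   `n`.
#' @method glance nnice_report
#' @export
glance.nnice_report <- function(x, ...) {
  overall <- x[x$level == "overall", c("r", "rmse", "loss", "n")]
  as_tibble(as.data.frame(overall))
}
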