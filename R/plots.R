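# Reporting figures: truth-vs-estimate scatter panels with least-squares
# fits. Pearson R alone can flatter an estimator whose regression slope is
# far from 1, so every panel is annotated with slope and intercept too.

#' Scatter data with per-panel regression statistics
#'
#' @param true `fraction_matrix` tibble or matrix of true fractions.
#' @param estimates `nnice_estimates` tibble from [aggregate_quantiles()].
#' @return A list: `points` (long tibble of truth/estimate pairs per cell
#'   type plus an all-types pooled panel) and `stats` (per-panel tibble of
#'   least-squares `slope`, `intercept`, `r`, `n`).
#' @export
scatter_data <- function(true, estimates) {
  tvals <- fraction_values(true)
  pts <- estimates |>
    dplyr::mutate(truth = mapply(function(s, ct) tvals[s, ct],
                                 .data$sample_id, .data$cell_type)) |>
    dplyr::select("sample_id", "cell_type", "truth", estimate = "mean")
  pooled <- dplyr::mutate(pts, cell_type = "All cell types")
  pts <- dplyr::bind_rows(pts, pooled)
  stats_tbl <- pts |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(
      slope = {
        fit <- lm(estimate ~ truth)
        unname(coef(fit)[2])
      },
      intercept = {
        fit <- lm(estimate ~ truth)
        unname(coef(fit)[1])
      },
      r = suppressWarnings(pearson_r(.data$truth, .data$estimate)),
      n = dplyr::n(),
      .groups = "drop")
  list(points = pts, stats = stats_tbl)
}

#' Truth-vs-estimate scatter plot
#'
#' One panel per cell type plus a pooled all-types panel; dashed identity
#' line, solid least-squares line, annotated R/slope/intercept.
#'
#' @inheritParams scatter_data
#' @return A ggplot object.
#' @export
plot_deconvolution <- function(true, estimates) {
  sd_ <- scatter_data(true, estimates)
  labels <- sd_$stats |>
    dplyr::mutate(label = sprintf("R = %.3f\nslope = %.2f\nint = %.2f",
                                  .data$r, .data$slope, .data$intercept))
  ggplot2::ggplot(sd_$points,
                  ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6, colour = "black") +
    ggplot2::geom_text(data = labels, size = 2.8, hjust = 0, vjust = 1,
                       ggplot2::aes(x = 0.02, y = 0.98,
                                    label = .data$label)) +
    ggplot2::facet_wrap(~cell_type) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "True fraction", y = "Estimated fraction") +
    ggplot2::theme_bw()
}

#' Write scatter-report figure files
#'
#' Saves one faceted figure of per-type panels plus the pooled panel, one
#' figure per quantile level, and the per-panel regression statistics as
#' a TSV.
#'
#' @param true `fraction_matrix` tibble or matrix of true fractions.
#' @param estimates `nnice_estimates` tibble.
#' @param out_dir Output directory.
#' @param device `"png"` or `"svg"`.
#' @return The per-panel statistics tibble, invisibly.
#' @export
scatter_report <- function(true, estimates, out_dir, device = "png") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sd_ <- scatter_data(true, estimates)
  p <- plot_deconvolution(true, estimates)
  ggplot2::ggsave(file.path(out_dir, paste0("scatter_by_type.", device)),
                  p, width = 8, height = 6, dpi = 150)
  write.table(as.data.frame(sd_$stats),
              file.path(out_dir, "panel_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sd_$stats)
}

#' Training-history plot
#'
#' Training and validation loss per epoch, faceted by cell type, one line
#' per quantile net.
#'
#' @param model A trained `nnice_model` (with `model$history`).
#' @return A ggplot object.
#' @export
plot_history <- function(model) {
  h <- model$history
  assert_that(!is.null(h) && nrow(h) > 0, "model has no training history")
  long <- tidyr::pivot_longer(h, cols = c("train_loss", "val_loss"),
                              names_to = "phase", values_to = "loss")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$epoch, y = .data$loss,
                               colour = factor(.data$quantile),
                               linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(colour = "quantile", linetype = NULL) +
    ggplot2::theme_bw()
}

#' Plot estimates against true fractions
#'
#' @param object An `nnice_estimates` tibble.
#' @param true True fractions (`fraction_matrix` tibble or matrix).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nnice_estimates
#' @export
autoplot.nnice_estimates <- function(object, true = NULL, ...) {
  assert_that(!is.null(true),
              "supply `true` fractions to plot estimates against")
  plot_deconvolution(true, object)
}

#' Plot a model's training history
#'
#' @param object A trained `nnice_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nnice_model
#' @export
autoplot.nnice_model <- function(object, ...) plot_history(object)
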