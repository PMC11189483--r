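# Training objectives of the quantile deconvolution networks: the softmax
# head kept for the legacy multi-output architecture, the Pearson/RMSE
# composite loss, the tilted (pinball) quantile loss, and the analytic
# gradients the hand-written optimizer consumes.

#' Shift-invariant softmax
#'
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`, computed after subtracting
#' `max(z)` so large inputs cannot overflow. Provided for the legacy
#' multi-output model head; the final per-cell-type networks do not use it.
#'
#' @param z Numeric vector with finite entries.
#' @return Numeric vector on the simplex (sums to 1).
#' @export
softmax <- function(z) {
  assert_that(all(is.finite(z)), "softmax requires finite entries")
  e <- exp(z - max(z))
  e / sum(e)
}

#' Pearson correlation between truth and estimate
#'
#' The centered cross-moment over the product of centered norms. Returns
#' `NA` (with a warning) when either vector is constant, in which case
#' callers fall back to the RMSE-only part of the composite loss.
#'
#' @param y True values (length >= 2).
#' @param yhat Estimates, same length.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_r <- function(y, yhat) {
  assert_that(length(y) == length(yhat), "length mismatch")
  assert_that(length(y) >= 2, "need at least 2 observations")
  yc <- y - mean(y)
  hc <- yhat - mean(yhat)
  denom <- sqrt(sum(hc^2) * sum(yc^2))
  if (denom == 0) {
    warning("correlation undefined for constant vector", call. = FALSE)
    return(NA_real_)
  }
  sum(hc * yc) / denom
}

#' Root-mean-square error
#'
#' @param y True values.
#' @param yhat Estimates, same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  assert_that(length(y) == length(yhat), "length mismatch")
  assert_that(length(y) >= 1, "need at least 1 observation")
  sqrt(mean((y - yhat)^2))
}

#' Composite correlation/RMSE loss
#'
#' `alpha * (1 - R) + (1 - alpha) * RMSE`, the weighted mix of the Pearson
#' correlation loss and the root-mean-square error, computed per
#' minibatch. When R is undefined (constant vector) the correlation term
#' is dropped and the RMSE-only value returned.
#'
#' @param y,yhat Paired truth/estimate vectors.
#' @param alpha_mix Weight on the correlation term, in `[0, 1]`
#'   (default 0.8).
#' @return Non-negative scalar loss.
#' @export
custom_loss <- function(y, yhat, alpha_mix = 0.8) {
  assert_that(alpha_mix >= 0 && alpha_mix <= 1, "alpha_mix must be in [0,1]")
  r <- suppressWarnings(pearson_r(y, yhat))
  if (is.na(r)) {
    return(rmse(y, yhat))
  }
  alpha_mix * (1 - r) + (1 - alpha_mix) * rmse(y, yhat)
}

#' Tilted (pinball) loss
#'
#' `max(q * xi, (q - 1) * xi)` for residual `xi`; the asymmetric loss
#' whose minimizer is the `q`-th conditional quantile. For a vector
#' residual it is applied elementwise and averaged.
#'
#' @param q Quantile level in (0, 1).
#' @param xi Residual(s).
#' @return Non-negative scalar.
#' @export
tilted_loss <- function(q, xi) {
  assert_that(q > 0 && q < 1, "q must be in (0, 1)")
  mean(pmax(q * xi, (q - 1) * xi))
}

#' Per-net training objective
#'
#' Two readings of "the composite loss nested inside the tilted loss":
#'
#' * `loss_mode = "signed"` (default): the mean pinball loss over the
#'   signed per-sample residuals `xi_i = y_i - yhat_i`, plus
#'   `alpha_mix * (1 - R)` on the batch as a correlation regularizer. This
#'   is genuine quantile regression — under-prediction is penalized
#'   `q/(1-q)` times more than over-prediction at level `q`, so the
#'   trained net estimates the `q`-th conditional quantile.
#' * `loss_mode = "literal"`: `tilted_loss(q, custom_loss(y, yhat,
#'   alpha_mix))` applied to the scalar non-negative batch loss, which
#'   degenerates to `q * custom_loss` (the max always picks the positive
#'   branch), so all quantile levels optimize proportional objectives.
#'   Retained for fidelity experiments.
#'
#' @param y,yhat Minibatch truth/estimate vectors.
#' @param q Quantile level in (0, 1).
#' @param alpha_mix Correlation weight (default 0.8).
#' @param loss_mode `"signed"` or `"literal"`.
#' @return Scalar objective value.
#' @export
training_objective <- function(y, yhat, q, alpha_mix = 0.8,
                               loss_mode = c("signed", "literal")) {
  loss_mode <- match.arg(loss_mode)
  if (loss_mode == "literal") {
    return(tilted_loss(q, custom_loss(y, yhat, alpha_mix)))
  }
  pin <- tilted_loss(q, y - yhat)
  r <- suppressWarnings(pearson_r(y, yhat))
  reg <- if (is.na(r)) 0 else alpha_mix * (1 - r)
  pin + reg
}

# Gradients with respect to yhat -------------------------------------------

# d R / d yhat (vector); NULL when R undefined.
grad_pearson <- function(y, yhat) {
  yc <- y - mean(y)
  hc <- yhat - mean(yhat)
  b <- sum(hc^2)
  c_ <- sum(yc^2)
  denom <- sqrt(b * c_)
  if (denom == 0) return(NULL)
  a <- sum(hc * yc)
  yc / denom - (a / b) * hc / denom
}

# d RMSE / d yhat.
grad_rmse <- function(y, yhat) {
  r <- rmse(y, yhat)
  if (r == 0) return(rep(0, length(y)))
  (yhat - y) / (length(y) * r)
}

# d training_objective / d yhat for either loss mode.
grad_objective <- function(y, yhat, q, alpha_mix, loss_mode) {
  n <- length(y)
  if (loss_mode == "literal") {
    cl <- custom_loss(y, yhat, alpha_mix)
    tilt <- if (cl >= 0) q else q - 1
    gp <- grad_pearson(y, yhat)
    gr <- grad_rmse(y, yhat)
    inner <- if (is.null(gp)) gr else {
      alpha_mix * (-gp) + (1 - alpha_mix) * gr
    }
    return(tilt * inner)
  }
  xi <- y - yhat
  # subgradient of mean pinball: xi > 0 -> -q/n ; xi < 0 -> (1-q)/n
  g <- ifelse(xi > 0, -q / n, ifelse(xi < 0, (1 - q) / n, 0))
  gp <- grad_pearson(y, yhat)
  if (!is.null(gp)) g <- g - alpha_mix * gp
  g
}
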