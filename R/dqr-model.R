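#' Model configuration
#'
#' Hyperparameters of the quantile deconvolution estimator: one
#' single-output dense network per (cell type, quantile) pair, each an
#' input layer of `n_features` connected to a `hidden_units` dense layer
#' with linear activations, then a 1-unit linear output whose bias is
#' constrained non-negative, with L2 regularization `l2_lambda` on the
#' weight kernels.
#'
#' @param n_features Input dimension (default 3000).
#' @param hidden_units Hidden layer width (default 300).
#' @param l2_lambda L2 penalty on weight kernels (default 1e-4).
#' @param quantiles Strictly increasing quantile levels in (0, 1)
#'   (default 0.10, 0.25, 0.50, 0.75, 0.90).
#' @param alpha_mix Weight of the correlation term in the composite loss
#'   (default 0.8).
#' @param loss_mode `"signed"` (per-sample pinball residuals; genuine
#'   quantile regression) or `"literal"` (pinball of the scalar batch
#'   loss). See [training_objective()].
#' @param epochs Maximum training epochs (default 30).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience Early-stopping patience on validation loss (default 5);
#'   best weights are restored.
#' @param seed Integer seed controlling initialization and batching.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_features = 3000, hidden_units = 300,
                         l2_lambda = 1e-4,
                         quantiles = c(0.10, 0.25, 0.50, 0.75, 0.90),
                         alpha_mix = 0.8,
                         loss_mode = c("signed", "literal"),
                         epochs = 30, batch_size = 64,
                         learning_rate = 1e-3, patience = 5, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  assert_that(all(diff(quantiles) > 0) && all(quantiles > 0) &&
                all(quantiles < 1),
              "quantiles must be strictly increasing in (0, 1)")
  assert_that(l2_lambda >= 0, "l2_lambda must be non-negative")
  assert_that(alpha_mix >= 0 && alpha_mix <= 1, "alpha_mix must be in [0,1]")
  structure(
    list(n_features = as.integer(n_features),
         hidden_units = as.integer(hidden_units),
         l2_lambda = l2_lambda, quantiles = quantiles,
         alpha_mix = alpha_mix, loss_mode = loss_mode,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, patience = as.integer(patience),
         seed = as.integer(seed)),
    class = "model_config"
  )
}

net_id <- function(cell_type, q) sprintf("%s|q%02d", cell_type, round(q * 100))

# Uniform Glorot initialization of one net's parameters.
init_net <- function(cell_type, q, config, seed) {
  with_seed(seed, {
    p <- config$n_features
    h <- config$hidden_units
    lim1 <- sqrt(6 / (p + h))
    lim2 <- sqrt(6 / (h + 1))
    list(cell_type = cell_type, q = q,
         W1 = matrix(runif(p * h, -lim1, lim1), nrow = p),
         b1 = rep(0, h),
         W2 = matrix(runif(h, -lim2, lim2), ncol = 1),
         b2 = 0)
  })
}

n_params_net <- function(net) {
  length(net$W1) + length(net$b1) + length(net$W2) + 1L
}

#' Build the quantile deconvolution model
#'
#' One independently initialized network per (cell type, quantile) pair —
#' `K * length(quantiles)` nets sharing the same feature set (with the
#' defaults, 6 pooled types x 5 quantiles = 30 nets of
#' 3000 x 300 + 300 + 300 + 1 = 900,601 parameters each).
#'
#' @param config A [model_config()].
#' @param cell_types Character vector of pooled cell-type names.
#' @param feature_set A `feature_set` (or character vector of gene IDs) of
#'   length `config$n_features`.
#' @return An object of class `nnice_model` (untrained; normalization
#'   statistics are fitted by [train_nnice()]).
#' @export
build_model <- function(config, cell_types, feature_set) {
  genes <- feature_genes(feature_set)
  assert_that(length(genes) == config$n_features,
              sprintf("feature set has %d genes but config expects %d",
                      length(genes), config$n_features))
  nets <- list()
  idx <- 0L
  for (ct in cell_types) {
    for (q in config$quantiles) {
      idx <- idx + 1L
      nets[[net_id(ct, q)]] <-
        init_net(ct, q, config, derive_seed(config$seed, idx))
    }
  }
  structure(
    list(nets = nets, cell_types = cell_types, feature_genes = genes,
         config = config, norm = NULL, history = NULL),
    class = "nnice_model"
  )
}

#' @export
print.nnice_model <- function(x, ...) {
  cat(sprintf(paste0("<nnice_model> %d cell types x %d quantiles = %d nets",
                     " (%s, %d features, %d hidden units)\n"),
              length(x$cell_types), length(x$config$quantiles),
              length(x$nets),
              if (is.null(x$norm)) "untrained" else "trained",
              x$config$n_features, x$config$hidden_units))
  invisible(x)
}

# Input normalization: log1p of counts-per-million, then per-feature
# standardization with statistics fitted on the training split only.
fit_normalization <- function(profiles) {
  z <- log1p_cpm(profiles)
  mu <- colMeans(z)
  sdv <- apply(z, 2, sd)
  sdv[sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

log1p_cpm <- function(profiles) {
  totals <- rowSums(profiles)
  totals[totals == 0] <- 1
  log1p(profiles / totals * 1e6)
}

apply_normalization <- function(profiles, norm) {
  z <- log1p_cpm(profiles)
  sweep(sweep(z, 2, norm$mean, "-"), 2, norm$sd, "/")
}

# Align a profiles matrix (samples x genes) to the model's feature order,
# zero-filling absent genes.
align_profiles <- function(profiles, genes) {
  assert_that(!is.null(colnames(profiles)), "profiles need gene column names")
  if (identical(colnames(profiles), genes)) return(profiles)
  idx <- match(genes, colnames(profiles))
  missing <- genes[is.na(idx)]
  if (length(missing) > 0) {
    warning(length(missing), " model features missing from profiles, ",
            "zero-filled", call. = FALSE)
  }
  out <- matrix(0, nrow = nrow(profiles), ncol = length(genes),
                dimnames = list(rownames(profiles), genes))
  out[, !is.na(idx)] <- profiles[, idx[!is.na(idx)], drop = FALSE]
  out
}

forward_net <- function(net, X) {
  H <- X %*% net$W1 + matrix(net$b1, nrow(X), length(net$b1), byrow = TRUE)
  as.numeric(H %*% net$W2 + net$b2)
}

# One net's full training loop: Adam on minibatches of the quantile
# objective, L2 on the weight kernels, output bias clamped >= 0 after
# every step, early stopping with best-weight restore.
train_net <- function(net, Xtr, ytr, Xval, yval, config, seed) {
  p <- nrow(net$W1); h <- ncol(net$W1)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  m <- list(W1 = matrix(0, p, h), b1 = rep(0, h),
            W2 = matrix(0, h, 1), b2 = 0)
  v <- m
  t_step <- 0
  n <- nrow(Xtr)
  history <- vector("list", config$epochs)
  best <- list(loss = Inf, net = net, epoch = 0L)
  wait <- 0L
  obj <- function(yy, hh) training_objective(yy, hh, net$q,
                                             config$alpha_mix,
                                             config$loss_mode)
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        if (length(idx) < 2) next   # batch objectives need >= 2 samples
        Xb <- Xtr[idx, , drop = FALSE]
        yb <- ytr[idx]
        Hb <- Xb %*% net$W1 +
          matrix(net$b1, length(idx), h, byrow = TRUE)
        yhat <- as.numeric(Hb %*% net$W2 + net$b2)
        loss <- suppressWarnings(obj(yb, yhat))
        if (!is.finite(loss)) {
          stop("non-finite training loss for net ",
               net_id(net$cell_type, net$q), " at epoch ", epoch,
               call. = FALSE)
        }
        batch_losses <- c(batch_losses, loss)
        g_yhat <- suppressWarnings(
          grad_objective(yb, yhat, net$q, config$alpha_mix,
                         config$loss_mode))
        # backprop through the two linear layers
        gW2 <- crossprod(Hb, g_yhat) + 2 * config$l2_lambda * net$W2
        gb2 <- sum(g_yhat)
        gH <- outer(g_yhat, as.numeric(net$W2))   # n x h
        gW1 <- crossprod(Xb, gH) + 2 * config$l2_lambda * net$W1
        gb1 <- colSums(gH)
        t_step <- t_step + 1
        corr1 <- 1 - beta1^t_step
        corr2 <- 1 - beta2^t_step
        step <- function(param, grad, slot) {
          m[[slot]] <<- beta1 * m[[slot]] + (1 - beta1) * grad
          v[[slot]] <<- beta2 * v[[slot]] + (1 - beta2) * grad^2
          param - lr * (m[[slot]] / corr1) /
            (sqrt(v[[slot]] / corr2) + eps)
        }
        net$W1 <- step(net$W1, gW1, "W1")
        net$b1 <- step(net$b1, gb1, "b1")
        net$W2 <- step(net$W2, gW2, "W2")
        net$b2 <- max(step(net$b2, gb2, "b2"), 0)  # non-negativity
      }
      val_hat <- forward_net(net, Xval)
      val_loss <- suppressWarnings(obj(yval, val_hat))
      history[[epoch]] <- tibble(
        cell_type = net$cell_type, quantile = net$q, epoch = epoch,
        train_loss = mean(batch_losses), val_loss = val_loss,
        val_r = suppressWarnings(pearson_r(yval, val_hat)),
        val_rmse = rmse(yval, val_hat))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, net = net, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  list(net = best$net, history = dplyr::bind_rows(history))
}

#' Train the quantile deconvolution model
#'
#' Fits every (cell type, quantile) network independently on the mapping
#' from a sample's expression profile to that cell type's true fraction,
#' using the net's quantile objective (see [training_objective()]), Adam,
#' minibatches, L2 on the weight kernels, and a non-negativity clamp on
#' the output bias after every step. Input profiles are log1p-CPM
#' transformed and standardized with statistics fitted on the training
#' split only. Training is deterministic given the config seed.
#'
#' @param model An `nnice_model` from [build_model()].
#' @param profiles Samples x genes numeric matrix (raw counts) with gene
#'   column names; reordered/zero-filled to the model's feature set.
#' @param fractions A `fraction_matrix` tibble (or samples x types matrix)
#'   with one column per model cell type.
#' @param val_frac Fraction of samples held out as the validation split
#'   (default 0.1), or supply `val_profiles`/`val_fractions` explicitly.
#' @param val_profiles,val_fractions Optional explicit validation set.
#' @return The trained `nnice_model`; per-epoch history in
#'   `model$history` (tibble: cell_type, quantile, epoch, train_loss,
#'   val_loss, val_r, val_rmse).
#' @export
train_nnice <- function(model, profiles, fractions, val_frac = 0.1,
                        val_profiles = NULL, val_fractions = NULL) {
  stopifnot(inherits(model, "nnice_model"))
  fvals <- fraction_values(fractions)
  assert_that(nrow(profiles) == nrow(fvals),
              "profiles and fractions disagree on sample count")
  missing_types <- setdiff(model$cell_types, colnames(fvals))
  assert_that(length(missing_types) == 0,
              paste0("fractions lack cell types: ",
                     paste(missing_types, collapse = ", ")))
  config <- model$config
  if (config$epochs == 0) {
    model$history <- tibble(cell_type = character(), quantile = numeric(),
                            epoch = integer(), train_loss = numeric(),
                            val_loss = numeric(), val_r = numeric(),
                            val_rmse = numeric())
    return(model)
  }
  X <- align_profiles(profiles, model$feature_genes)
  if (is.null(val_profiles)) {
    n <- nrow(X)
    n_val <- max(2L, round(val_frac * n))
    assert_that(n - n_val >= 2, "too few samples to split off validation")
    val_idx <- with_seed(derive_seed(config$seed, 7777L),
                         sample.int(n, n_val))
    Xval_raw <- X[val_idx, , drop = FALSE]
    fval_val <- fvals[val_idx, , drop = FALSE]
    X <- X[-val_idx, , drop = FALSE]
    fvals <- fvals[-val_idx, , drop = FALSE]
  } else {
    Xval_raw <- align_profiles(val_profiles, model$feature_genes)
    fval_val <- fraction_values(val_fractions)
  }
  model$norm <- fit_normalization(X)
  Xtr <- apply_normalization(X, model$norm)
  Xval <- apply_normalization(Xval_raw, model$norm)
  histories <- vector("list", length(model$nets))
  for (i in seq_along(model$nets)) {
    net <- model$nets[[i]]
    fit <- train_net(net, Xtr, fvals[, net$cell_type], Xval,
                     fval_val[, net$cell_type], config,
                     seed = derive_seed(config$seed, 100000L + i))
    model$nets[[i]] <- fit$net
    histories[[i]] <- fit$history
  }
  model$history <- dplyr::bind_rows(histories)
  model
}

#' Predict per-quantile cell-type fractions
#'
#' Runs every (cell type, quantile) net on the supplied bulk profiles.
#' Raw net outputs are clipped to `[0, 1]`; there is no coupling across
#' cell types and no renormalization (see [aggregate_quantiles()]).
#'
#' @param object A trained `nnice_model`.
#' @param profiles Samples x genes numeric matrix (raw counts) with gene
#'   column names.
#' @param ... Unused.
#' @return A 3-d array `samples x cell_types x quantiles` with dimnames.
#' @export
predict.nnice_model <- function(object, profiles, ...) {
  assert_that(!is.null(object$norm), "model has not been trained")
  X <- apply_normalization(align_profiles(profiles, object$feature_genes),
                           object$norm)
  qs <- object$config$quantiles
  out <- array(NA_real_,
               dim = c(nrow(X), length(object$cell_types), length(qs)),
               dimnames = list(rownames(profiles), object$cell_types,
                               paste0("q", round(qs * 100))))
  for (net in object$nets) {
    qi <- match(net$q, qs)
    out[, net$cell_type, qi] <- pmin(pmax(forward_net(net, X), 0), 1)
  }
  out
}

#' Aggregate quantile estimates into point estimates and intervals
#'
#' The point estimate is the unweighted mean of the per-quantile outputs
#' (averaging across quantiles gives a less biased point estimate than
#' any single quantile); the uncertainty interval is the pair of
#' lowest/highest-quantile net outputs. Because the per-type nets are
#' independent, point-estimate rows are not renormalized to the simplex
#' unless requested. Quantile crossing (a lower-quantile net predicting
#' above a higher one) is reported, not corrected, unless
#' `sort_quantiles` is set.
#'
#' @param estimates Array from [predict.nnice_model()].
#' @param renormalize If `TRUE`, rescale each sample's point-estimate row
#'   to sum to 1 (default `FALSE`).
#' @param sort_quantiles If `TRUE`, sort the per-(sample, type) quantile
#'   outputs increasingly before aggregating (default `FALSE`).
#' @return A tibble of class `nnice_estimates`: `sample_id`, `cell_type`,
#'   one column per quantile (`q10`, ...), `mean`, `lower`, `upper`.
#' @export
aggregate_quantiles <- function(estimates, renormalize = FALSE,
                                sort_quantiles = FALSE) {
  dn <- dimnames(estimates)
  n <- dim(estimates)[1]
  if (sort_quantiles) {
    estimates <- aperm(apply(estimates, c(1, 2), sort), c(2, 3, 1))
    dimnames(estimates) <- dn
  }
  point <- apply(estimates, c(1, 2), mean)
  if (renormalize) {
    rs <- rowSums(point)
    rs[rs == 0] <- 1
    point <- point / rs
  }
  sample_ids <- dn[[1]] %||% sprintf("sample%05d", seq_len(n))
  rows <- lapply(seq_along(dn[[2]]), function(k) {
    qcols <- as.data.frame(estimates[, k, , drop = TRUE])
    if (n == 1) qcols <- as.data.frame(t(qcols))
    names(qcols) <- dn[[3]]
    dplyr::bind_cols(
      tibble(sample_id = sample_ids, cell_type = dn[[2]][k]),
      qcols,
      tibble(mean = unname(point[, k]),
             lower = unname(estimates[, k, 1]),
             upper = unname(estimates[, k, dim(estimates)[3]])))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("nnice_estimates", class(tibble()))
  out
}

#' Point-estimate fractions from aggregated estimates
#'
#' @param estimates An `nnice_estimates` tibble.
#' @return A samples x cell-types matrix of quantile-averaged fractions.
#' @export
estimated_fractions <- function(estimates) {
  wide <- tidyr::pivot_wider(estimates[, c("sample_id", "cell_type", "mean")],
                             names_from = "cell_type",
                             values_from = "mean")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}

# Serialization -------------------------------------------------------------

#' Save / load a trained model as a plain-text bundle
#'
#' The bundle directory holds one TSV of flattened parameters per net, the
#' feature list, the normalization statistics and a JSON manifest echoing
#' the configuration — portable and human-inspectable.
#'
#' @param model A trained `nnice_model`.
#' @param directory Bundle directory.
#' @return `directory` (write) / an `nnice_model` (read).
#' @export
write_model <- function(model, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  writeLines(model$feature_genes, file.path(directory, "features.txt"))
  if (!is.null(model$norm)) {
    write.table(data.frame(gene = model$feature_genes,
                           mean = model$norm$mean, sd = model$norm$sd),
                file.path(directory, "normalization.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (id in names(model$nets)) {
    net <- model$nets[[id]]
    safe <- gsub("[^A-Za-z0-9]+", "_", id)
    con <- gzfile(file.path(directory, paste0("net_", safe, ".tsv.gz")))
    writeLines(c(paste(c(net$cell_type, net$q, nrow(net$W1),
                         ncol(net$W1)), collapse = "\t"),
                 paste(format(c(as.numeric(net$W1), net$b1,
                                as.numeric(net$W2), net$b2),
                              digits = 17, trim = TRUE, scientific = TRUE),
                       collapse = "\t")), con)
    close(con)
  }
  manifest <- unclass(model$config)
  manifest$cell_types <- model$cell_types
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}

#' @rdname write_model
#' @export
read_model <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  config <- model_config(
    n_features = manifest$n_features, hidden_units = manifest$hidden_units,
    l2_lambda = manifest$l2_lambda, quantiles = manifest$quantiles,
    alpha_mix = manifest$alpha_mix, loss_mode = manifest$loss_mode,
    epochs = manifest$epochs, batch_size = manifest$batch_size,
    learning_rate = manifest$learning_rate, patience = manifest$patience,
    seed = manifest$seed)
  genes <- readLines(file.path(directory, "features.txt"))
  model <- build_model(config, manifest$cell_types, genes)
  norm_path <- file.path(directory, "normalization.tsv")
  if (file.exists(norm_path)) {
    nt <- read.table(norm_path, sep = "\t", header = TRUE)
    model$norm <- list(mean = setNames(nt$mean, nt$gene),
                       sd = setNames(nt$sd, nt$gene))
  }
  for (id in names(model$nets)) {
    safe <- gsub("[^A-Za-z0-9]+", "_", id)
    lines <- readLines(file.path(directory, paste0("net_", safe, ".tsv.gz")))
    header <- strsplit(lines[1], "\t")[[1]]
    p <- as.integer(header[3]); h <- as.integer(header[4])
    theta <- as.numeric(strsplit(lines[2], "\t")[[1]])
    net <- model$nets[[id]]
    net$W1 <- matrix(theta[seq_len(p * h)], p, h)
    net$b1 <- theta[p * h + seq_len(h)]
    net$W2 <- matrix(theta[p * h + h + seq_len(h)], ncol = 1)
    net$b2 <- theta[p * h + 2 * h + 1]
    model$nets[[id]] <- net
  }
  model
}
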