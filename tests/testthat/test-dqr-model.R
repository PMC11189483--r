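test_that("model construction matches the stated architecture arithmetic", {
  # full-size net: 3000 x 300 + 300 + 300 + 1 parameters
  cfg <- model_config(n_features = 3000, hidden_units = 300,
                      quantiles = 0.5, seed = 1L)
  m <- build_model(cfg, "B cell", sprintf("g%04d", 1:3000))
  expect_length(m$nets, 1)
  expect_equal(nnice:::n_params_net(m$nets[[1]]), 900601L)

  # tiny net: 1 x 2 + 1 + 1 + 1 = 5
  cfg2 <- model_config(n_features = 2, hidden_units = 1, quantiles = 0.5)
  m2 <- build_model(cfg2, "A", c("g1", "g2"))
  expect_equal(nnice:::n_params_net(m2$nets[[1]]), 5L)

  # default quantile set over six types -> 30 nets
  cfg3 <- model_config(n_features = 10, hidden_units = 4, seed = 2L)
  m3 <- build_model(cfg3, c("B cell", "CD4 T cell", "CD8 T cell",
                            "Myeloid", "NK cell", "Other"),
                    sprintf("g%02d", 1:10))
  expect_length(m3$nets, 30)
  expect_equal(unname(sapply(m3$nets, `[[`, "cell_type")),
               rep(c("B cell", "CD4 T cell", "CD8 T cell", "Myeloid",
                     "NK cell", "Other"), each = 5))
})

test_that("initialization and training are deterministic given the seed", {
  cfg <- model_config(n_features = 8, hidden_units = 3, epochs = 3,
                      batch_size = 8, seed = 10L)
  fs <- sprintf("g%02d", 1:8)
  expect_identical(build_model(cfg, c("A", "B"), fs),
                   build_model(cfg, c("A", "B"), fs))

  set.seed(1)
  x <- matrix(rpois(40 * 8, 20), 40, dimnames = list(NULL, fs))
  fr <- matrix(runif(80), 40, 2, dimnames = list(NULL, c("A", "B")))
  fr <- fr / rowSums(fr)
  m1 <- train_nnice(build_model(cfg, c("A", "B"), fs), x, fr)
  m2 <- train_nnice(build_model(cfg, c("A", "B"), fs), x, fr)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$nets, m2$nets)
})

test_that("zero epochs leave the model untouched with an empty history", {
  cfg <- model_config(n_features = 4, hidden_units = 2, epochs = 0,
                      seed = 3L)
  fs <- paste0("g", 1:4)
  m <- build_model(cfg, "A", fs)
  x <- matrix(rpois(20, 5), 5, 4, dimnames = list(NULL, fs))
  fr <- matrix(runif(5), 5, 1, dimnames = list(NULL, "A"))
  trained <- train_nnice(m, x, fr)
  expect_identical(trained$nets, m$nets)
  expect_equal(nrow(trained$history), 0)
})

test_that("training reduces validation loss and keeps the output bias non-negative", {
  pb <- small_pseudobulk()
  cfg <- model_config(n_features = 300, hidden_units = 8,
                      quantiles = c(0.25, 0.5, 0.75), epochs = 10,
                      patience = 10, seed = 6L)
  m <- build_model(cfg, colnames(fraction_values(pb$train$fractions)),
                   colnames(pb$train$profiles))
  m <- train_nnice(m, pb$train$profiles, pb$train$fractions)
  h <- m$history
  first <- h[h$epoch == 1, ]
  last <- dplyr::summarise(
    dplyr::group_by(h, .data$cell_type, .data$quantile),
    final = .data$val_loss[which.max(.data$epoch)], .groups = "drop")
  joined <- dplyr::left_join(first, last, by = c("cell_type", "quantile"))
  expect_true(all(joined$final < joined$val_loss))
  expect_true(all(vapply(m$nets, function(n) n$b2 >= 0, logical(1))))
})

test_that("prediction clips to the unit interval and respects row identity", {
  pb <- small_pseudobulk()
  cfg <- model_config(n_features = 300, hidden_units = 8,
                      quantiles = c(0.1, 0.5, 0.9), epochs = 5,
                      patience = 10, seed = 8L)
  m <- build_model(cfg, colnames(fraction_values(pb$train$fractions)),
                   colnames(pb$train$profiles))
  m <- train_nnice(m, pb$train$profiles, pb$train$fractions)
  est <- predict(m, pb$test$profiles)
  expect_equal(dim(est), c(60L, 6L, 3L))
  expect_true(all(est >= 0 & est <= 1))
  # duplicated input rows give duplicated outputs
  dup <- pb$test$profiles[c(1, 1, 2), , drop = FALSE]
  est_dup <- predict(m, dup)
  expect_equal(est_dup[1, , ], est_dup[2, , ])
  # an untrained model refuses to predict
  expect_error(predict(build_model(cfg, "A",
                                   colnames(pb$train$profiles)),
                       pb$test$profiles), "trained")
})

test_that("quantile aggregation averages, bounds, and optionally renormalizes", {
  est <- array(0, dim = c(2, 2, 5),
               dimnames = list(c("s1", "s2"), c("A", "B"),
                               paste0("q", c(10, 25, 50, 75, 90))))
  est[1, 1, ] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  est[1, 2, ] <- 0.2
  est[2, 1, ] <- 0.6
  est[2, 2, ] <- 0.4
  agg <- aggregate_quantiles(est)
  a11 <- agg[agg$sample_id == "s1" & agg$cell_type == "A", ]
  expect_equal(a11$mean, 0.3)
  expect_equal(a11$lower, 0.1)
  expect_equal(a11$upper, 0.5)
  a12 <- agg[agg$sample_id == "s1" & agg$cell_type == "B", ]
  expect_equal(a12$upper - a12$lower, 0)   # all quantiles equal
  # renormalization leaves an already-normalized row unchanged
  agg2 <- aggregate_quantiles(est, renormalize = TRUE)
  s2 <- agg2[agg2$sample_id == "s2", ]
  expect_equal(sort(s2$mean), c(0.4, 0.6))
  # fraction extraction round-trips the point estimates
  fm <- estimated_fractions(agg)
  expect_equal(fm["s1", "A"], 0.3)
  # sorting repairs crossed quantiles
  est[2, 1, ] <- c(0.5, 0.4, 0.3, 0.2, 0.1)
  sorted <- aggregate_quantiles(est, sort_quantiles = TRUE)
  s21 <- sorted[sorted$sample_id == "s2" & sorted$cell_type == "A", ]
  expect_equal(s21$lower, 0.1)
  expect_equal(s21$upper, 0.5)
})

test_that("model bundles round-trip through the plain-text serialization", {
  pb <- small_pseudobulk()
  cfg <- model_config(n_features = 300, hidden_units = 6,
                      quantiles = c(0.5, 0.9), epochs = 3, seed = 12L)
  m <- build_model(cfg, colnames(fraction_values(pb$train$fractions)),
                   colnames(pb$train$profiles))
  m <- train_nnice(m, pb$train$profiles, pb$train$fractions)
  dir <- withr::local_tempdir()
  write_model(m, dir)
  back <- read_model(dir)
  expect_equal(predict(back, pb$test$profiles),
               predict(m, pb$test$profiles), tolerance = 1e-12)
  expect_equal(back$config$quantiles, cfg$quantiles)
})

test_that("tidiers summarize nets and training state", {
  cfg <- model_config(n_features = 5, hidden_units = 2,
                      quantiles = c(0.5, 0.9), seed = 2L)
  m <- build_model(cfg, c("A", "B"), paste0("g", 1:5))
  td <- tidy(m)
  expect_equal(nrow(td), 4)
  expect_true(all(td$n_params == 5 * 2 + 2 + 2 + 1))
  expect_true(all(is.na(td$val_loss)))
  gl <- glance(m)
  expect_false(gl$trained)
  expect_equal(gl$n_nets, 4)
})
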