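test_that("true-fraction normalization zero-fills and rescales rows", {
  raw <- tibble::tibble(sample_id = c("s1", "s2"),
                        A = c(0.2, 0.3), B = c(NA, 0.3), C = c(0.6, 0.4))
  fr <- normalize_true_fractions(raw)
  vals <- fraction_values(fr)
  expect_equal(unname(vals["s1", ]), c(0.25, 0, 0.75))
  # a row already on the simplex with no gaps is untouched
  expect_equal(unname(vals["s2", ]), c(0.3, 0.3, 0.4))
  expect_error(normalize_true_fractions(
    rbind(c(0, 0, 0), c(1, 1, 1))), "all-zero")
  expect_error(normalize_true_fractions(
    rbind(c(-0.1, 0.5, 0.6))), "negative")
})

test_that("cross-validation folds partition samples into near-equal chunks", {
  plan <- make_cv_folds(468, k = 10, seed = 2L)
  sizes <- as.numeric(table(plan$fold))
  expect_setequal(sizes, c(46, 47))
  expect_equal(sum(sizes), 468)
  expect_equal(sort(unique(plan$fold)), 1:10)
  # leave-one-out at n = k
  loo <- make_cv_folds(10, k = 10, seed = 3L)
  expect_equal(sort(loo$fold), 1:10)
  expect_error(make_cv_folds(5, k = 10), "< k")
  # deterministic given seed
  expect_identical(make_cv_folds(50, 5, seed = 9L),
                   make_cv_folds(50, 5, seed = 9L))
})

test_that("cross-validation produces one out-of-fold estimate per sample", {
  pb <- small_pseudobulk()
  profiles <- pb$train$profiles[1:40, ]
  fvals <- fraction_values(pb$train$fractions)[1:40, ]
  cfg <- model_config(n_features = 300, hidden_units = 4,
                      quantiles = c(0.5), epochs = 3, batch_size = 16,
                      seed = 5L)
  plan <- make_cv_folds(40, k = 2, seed = 6L)
  cv <- run_cv(profiles, fvals, colnames(profiles), cfg, plan)
  expect_equal(dim(cv$estimates), c(40L, 6L, 1L))
  expect_false(anyNA(cv$estimates))
  expect_true(all(is.finite(glance(cv$report)$r)))
  # each sample's estimate comes from the model that never saw it: spot
  # check by retraining fold 1's model and comparing its predictions
  fold_cfg <- cfg
  fold_cfg$seed <- nnice:::derive_seed(cfg$seed, 1L)
  m1 <- build_model(fold_cfg, colnames(fvals), colnames(profiles))
  m1 <- train_nnice(m1, profiles[plan$fold != 1, ],
                    fvals[plan$fold != 1, ])
  expect_equal(cv$estimates[plan$fold == 1, , , drop = FALSE],
               predict(m1, profiles[plan$fold == 1, ]))
})

test_that("evaluation metrics hit their closed forms on hand fixtures", {
  # perfect estimates at every quantile
  truth <- cbind(A = c(0.1, 0.4, 0.2, 0.3), B = c(0.9, 0.6, 0.8, 0.7))
  rownames(truth) <- paste0("s", 1:4)
  perfect <- array(rep(truth, 2), dim = c(4, 2, 2),
                   dimnames = list(rownames(truth), colnames(truth),
                                   c("q25", "q75")))
  rep1 <- evaluate_predictions(truth, perfect, alpha_mix = 0.8)
  expect_true(all(rep1$r == 1))
  expect_true(all(rep1$rmse == 0))
  expect_true(all(rep1$loss == 0))

  # anticorrelated single-type toy: R = -1
  anti_truth <- cbind(A = c(0.1, 0.9))
  rownames(anti_truth) <- c("s1", "s2")
  anti <- array(c(0.9, 0.1), dim = c(2, 1, 1),
                dimnames = list(c("s1", "s2"), "A", "q50"))
  rep2 <- evaluate_predictions(anti_truth, anti)
  expect_equal(rep2$r[rep2$level == "overall"], -1)

  # hand-computed 4-sample, 2-type fixture (single quantile):
  # per-type A: y=(.1,.4,.2,.3) vs est=(.2,.3,.1,.4) -> R=0.6, RMSE=0.1
  est <- array(0, dim = c(4, 2, 1),
               dimnames = list(rownames(truth), colnames(truth), "q50"))
  est[, "A", 1] <- c(0.2, 0.3, 0.1, 0.4)
  est[, "B", 1] <- c(0.8, 0.7, 0.9, 0.6)
  rep3 <- evaluate_predictions(truth, est, alpha_mix = 0.8)
  row_a <- rep3[rep3$level == "cell_type" & rep3$cell_type == "A", ]
  expect_equal(row_a$r, 0.6)
  expect_equal(row_a$rmse, 0.1)
  expect_equal(row_a$loss, 0.8 * (1 - 0.6) + 0.2 * 0.1)
  expect_equal(row_a$n, 4L)
})

test_that("overall R pools the concatenation, not the mean of per-type Rs", {
  # within each type the estimate is a pure shift (R = 1 per type), but
  # the shifts are opposite, so the pooled R must be well below 1
  truth <- cbind(A = c(0.1, 0.2, 0.3, 0.4), B = c(0.4, 0.3, 0.2, 0.1))
  rownames(truth) <- paste0("s", 1:4)
  est <- array(0, dim = c(4, 2, 1),
               dimnames = list(rownames(truth), c("A", "B"), "q50"))
  est[, "A", 1] <- truth[, "A"] + 0.5
  est[, "B", 1] <- truth[, "B"] - 0.05
  rep_ <- evaluate_predictions(truth, est)
  per_type <- rep_[rep_$level == "cell_type", ]
  expect_equal(per_type$r, c(1, 1))
  pooled <- rep_[rep_$level == "overall", ]
  oracle <- cor(as.numeric(truth), c(truth[, "A"] + 0.5,
                                     truth[, "B"] - 0.05))
  expect_equal(pooled$r, oracle)
  expect_lt(pooled$r, 0.99 * mean(per_type$r))
})

test_that("constant truth columns are reported as missing, not zero", {
  truth <- cbind(A = c(0.5, 0.5, 0.5), B = c(0.2, 0.3, 0.5))
  rownames(truth) <- paste0("s", 1:3)
  est <- array(runif(6), dim = c(3, 2, 1),
               dimnames = list(rownames(truth), c("A", "B"), "q50"))
  rep_ <- evaluate_predictions(truth, est)
  row_a <- rep_[rep_$level == "cell_type" & rep_$cell_type == "A", ]
  expect_true(is.na(row_a$r))
  expect_true(is.na(row_a$loss))
  expect_false(is.na(row_a$rmse))
})

test_that("reports round-trip through the long-format serialization", {
  truth <- cbind(A = c(0.1, 0.4, 0.2), B = c(0.9, 0.6, 0.8))
  rownames(truth) <- paste0("s", 1:3)
  est <- array(runif(12), dim = c(3, 2, 2),
               dimnames = list(rownames(truth), c("A", "B"),
                               c("q25", "q75")))
  rep_ <- evaluate_predictions(truth, est, alpha_mix = 0.7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep_, path)
  back <- read_report(path)
  expect_equal(tidy(back), tidy(rep_))
  js <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path),
                                   ".json"))
  expect_equal(js$overall$r, glance(rep_)$r)
})

test_that("scatter panels carry least-squares lines with closed-form slopes", {
  # 3-point fixture with known least squares: x=(0,1,2), y=(0,2,3)
  # slope = cov/var = 1.5, intercept = mean(y) - slope*mean(x) = 1/6
  truth <- cbind(A = c(0, 1, 2) / 2)
  rownames(truth) <- paste0("s", 1:3)
  est_tbl <- tibble::tibble(
    sample_id = rownames(truth), cell_type = "A",
    q50 = c(0, 2, 3) / 2, mean = c(0, 2, 3) / 2,
    lower = c(0, 2, 3) / 2, upper = c(0, 2, 3) / 2)
  class(est_tbl) <- c("nnice_estimates", class(tibble::tibble()))
  sd_ <- scatter_data(truth, est_tbl)
  row_a <- sd_$stats[sd_$stats$cell_type == "A", ]
  expect_equal(row_a$slope, 1.5)
  expect_equal(row_a$intercept, 1 / 12)
  expect_equal(row_a$r, cor(c(0, 1, 2), c(0, 2, 3)))

  # identity data annotates slope 1, intercept 0
  est_id <- dplyr::mutate(est_tbl, q50 = truth[, "A"],
                          mean = truth[, "A"],
                          lower = truth[, "A"], upper = truth[, "A"])
  class(est_id) <- c("nnice_estimates", class(tibble::tibble()))
  sd_id <- scatter_data(truth, est_id)
  expect_equal(sd_id$stats$slope, c(1, 1))
  expect_equal(sd_id$stats$intercept, c(0, 0), tolerance = 1e-12)

  # figure files land on disk
  dir <- withr::local_tempdir()
  stats_out <- scatter_report(truth, est_tbl, dir)
  expect_true(file.exists(file.path(dir, "scatter_by_type.png")))
  expect_true(file.exists(file.path(dir, "panel_stats.tsv")))
  expect_equal(nrow(stats_out), 2)   # per-type panel + pooled panel
})
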