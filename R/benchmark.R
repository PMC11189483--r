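#' End-to-end pseudo-bulk deconvolution benchmark
#'
#' Runs the whole pipeline on synthetic data at desk scale: generate a
#' labeled single-cell reference (10 fine immune types pooled to 6
#' lineages), apply the standard QC filter, split cells to avoid
#' selection/simulation leakage, pick the feature set from an
#' immune-gene list and the variability ranking, simulate training and
#' held-out pseudo-bulk mixtures with Dirichlet ground truth, train the
#' per-(cell type, quantile) networks, and evaluate quantile-averaged
#' estimates on the held-out mixtures.
#'
#' @param seed Integer master seed; every stage derives its own stream
#'   from it.
#' @param n_genes,n_cell_types,cells_per_type,marker_fold,dropout_rate
#'   Reference generator settings (defaults 1000 genes, 10 types,
#'   300 cells/type, fold 5, dropout 0.2).
#' @param n_features Features selected for the model input (default 300).
#' @param n_train,n_test Pseudo-bulk training / held-out sample counts
#'   (defaults 2000 / 500).
#' @param C Cells per pseudo-bulk sample (default 500).
#' @param dirichlet_alpha Dirichlet concentration (default 1).
#' @param hidden_units,epochs Model size and training length (defaults
#'   64 / 30).
#' @param loss_mode Training objective mode (default `"signed"`).
#' @return A list: `model` (trained `nnice_model`), `report`
#'   (`nnice_report` on the held-out set), `estimates`
#'   (`nnice_estimates`), `test_fractions`, `feature_set`, and `overall`
#'   (one-row tibble with the pooled held-out R/RMSE/loss).
#' @export
run_benchmark <- function(seed = 1L, n_genes = 1000, n_cell_types = 10,
                          cells_per_type = 300, marker_fold = 5,
                          dropout_rate = 0.2, n_features = 300,
                          n_train = 2000, n_test = 500, C = 500,
                          dirichlet_alpha = 1, hidden_units = 64,
                          epochs = 30, loss_mode = "signed") {
  seed <- as.integer(seed) %% 100000L
  sc_cfg <- synthetic_config(n_genes = n_genes,
                             n_cell_types = n_cell_types,
                             cells_per_type = cells_per_type,
                             marker_fold = marker_fold,
                             dropout_rate = dropout_rate,
                             seed = derive_seed(seed, 1L))
  sig <- generate_signatures(sc_cfg)
  cells <- simulate_cells(sig, sc_cfg)
  qc <- compute_qc(cells)
  cells <- filter_cells(cells, qc, min_genes = 200, max_genes = 3000,
                        max_mito_pct = 5)
  cells$labels <- pool_cell_types(cells$labels)
  split <- split_reference(cells, 0.5, seed = derive_seed(seed, 2L))

  ranked <- rank_variable_genes(split$selection)
  gene_list_path <- tempfile(fileext = ".txt")
  on.exit(unlink(gene_list_path), add = TRUE)
  make_immune_gene_list(sig, gene_list_path, nonmarker_frac = 0.5,
                        seed = derive_seed(seed, 3L))
  immune <- read_gene_list(gene_list_path)
  fs <- select_features(ranked, immune, n_features = n_features)

  train_ds <- simulate_dataset(split$simulation, n_train, C = C,
                               dirichlet_alpha = dirichlet_alpha,
                               seed = derive_seed(seed, 4L))
  test_ds <- simulate_dataset(split$simulation, n_test, C = C,
                              dirichlet_alpha = dirichlet_alpha,
                              seed = derive_seed(seed, 5L))

  cfg <- model_config(n_features = n_features,
                      hidden_units = hidden_units, epochs = epochs,
                      loss_mode = loss_mode,
                      seed = derive_seed(seed, 6L))
  model <- build_model(cfg, sort(unique(cells$labels)), fs)
  model <- train_nnice(model, train_ds$profiles, train_ds$fractions)

  est_array <- predict(model, test_ds$profiles)
  estimates <- aggregate_quantiles(est_array)
  report <- evaluate_predictions(test_ds$fractions, est_array,
                                 alpha_mix = cfg$alpha_mix)
  list(model = model, report = report, estimates = estimates,
       test_fractions = test_ds$fractions, feature_set = fs,
       overall = glance(report))
}
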