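#' Run the full generate–optimize–train–evaluate pipeline
#'
#' End-to-end orchestration: (1) generate a labeled synthetic dataset,
#' (2) grid-search per-spectrum optimal `(lambda, tau)` with warm-start
#' chaining, (3) split 8:1:1 stratified by shape, (4) train the PCA-RF
#' parameter predictor on the training split, (5) evaluate it on the test
#' split, and summarize: per-shape MAE/PI for the default-parameter (DP),
#' optimized (OP), log/linear-center (LOC/LIC) and ML fits, plus the
#' `Pct(PI_ML >= 70)` / `Pct(PI_ML >= 80)` success tables.
#'
#' @param shapes Shape codes to include.
#' @param n_per_shape Spectra per shape.
#' @param seed Master seed for all stochastic stages.
#' @param config Grid-search configuration.
#' @param n_points Grid length of generated spectra.
#' @param num_trees,pca_var Predictor settings.
#' @param verbose Print stage timings.
#' @return A list: `dataset` (with `split` column), `optima` (per-spectrum
#'   grid-search records), `model`, `test_records` (per-spectrum ML
#'   evaluation), `shape_summary`, `pct_table`, `region` (the parameter
#'   region fit), and `centers` (LOC/LIC pairs).
#' @export
run_pipeline <- function(shapes = shape_codes(), n_per_shape = 50L,
                         seed = 1L, config = grid_search_config(),
                         n_points = 1024L, num_trees = 100L,
                         pca_var = 0.995, verbose = FALSE) {
  stage <- function(label, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    if (verbose) {
      message(sprintf("[%s] %.1f s", label,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    out
  }
  dataset <- stage("generate", generate_dataset(
    shapes = shapes, n_per_shape = n_per_shape, seed = seed,
    n_points = n_points))
  optima <- stage("optimize", optimize_dataset(dataset, config))
  dataset <- stage("split", split_dataset(dataset, seed = seed))
  train_rows <- dataset[dataset$split == "train", ]
  test_rows <- dataset[dataset$split == "test", ]
  model <- stage("train", train_param_predictor(
    train_rows, optima, num_trees = num_trees, pca_var = pca_var,
    seed = seed))
  test_records <- stage("evaluate", evaluate_predictor(
    model, test_rows, labels = optima))
  centers <- loc_lic(
    tibble(lambda = optima$lambda_star, tau = optima$tau_star))
  center_recs <- stage("centers", evaluate_fixed_params(
    dataset, centers))
  region <- fit_parameter_region(
    tibble(lambda = optima$lambda_star, tau = optima$tau_star))
  op_summary <- summarize_by_shape(optima)
  ml_summary <- summarize_by_shape(test_records)
  pct_table <- if (nrow(test_records) == 0) {
    tibble(shape_label = character(), pct_70 = numeric(), pct_80 = numeric())
  } else {
    test_records |>
      group_by(.data$shape_label) |>
      summarise(pct_70 = pct_above(.data$pi_ml, 70),
                pct_80 = pct_above(.data$pi_ml, 80), .groups = "drop")
  }
  list(dataset = dataset, optima = optima, model = model,
       test_records = test_records,
       shape_summary = dplyr::left_join(
         op_summary, ml_summary, by = "shape_label",
         suffix = c("_op", "_ml")),
       center_records = center_recs,
       pct_table = pct_table, region = region, centers = centers)
}

#' Score fixed parameter pairs over a dataset
#'
#' Evaluates fixed `(lambda, tau)` strategies (e.g. the LOC/LIC centers)
#' on every spectrum: MAE of the `p = 2` fit at those parameters against
#' the true baseline, and PI versus the default-parameter reference.
#'
#' @param dataset Nested dataset with true baselines.
#' @param params Tibble with `strategy`, `lambda`, `tau` columns.
#' @return Per-spectrum, per-strategy tibble with `mae` and `pi`.
#' @export
evaluate_fixed_params <- function(dataset, params) {
  rows <- purrr::pmap(
    list(dataset$id, dataset$shape_label, dataset$spectrum),
    function(id, shape, sp) {
      check_spectrum(sp, need_truth = TRUE)
      dp <- airpls(sp, lambda = 100, tau = 1e-3, p = 1L)
      mae_dp <- mae(dp$data$baseline, sp$true_baseline)
      purrr::pmap(list(params$strategy, params$lambda, params$tau),
                  function(st, l, t) {
        fit <- airpls(sp, lambda = l, tau = t, p = 2L)
        m <- mae(fit$data$baseline, sp$true_baseline)
        tibble(id = id, shape_label = shape, strategy = st,
               mae = m, mae_dp = mae_dp,
               pi = percentage_improvement(mae_dp, m))
      }) |> dplyr::bind_rows()
    })
  dplyr::bind_rows(rows)
}
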