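#' Stratified train/validation/test split
#'
#' Splits a nested dataset by shape label in the given ratios (8:1:1 by
#' default), assigning the rounding remainder to the training set.
#' Deterministic under `seed`.
#'
#' @param dataset Nested tibble (one row per spectrum, `shape_label` column).
#' @param ratios Train/validation/test fractions summing to 1.
#' @param seed Integer seed for the within-shape shuffle.
#' @return The dataset with an added `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
#' @examples
#' ds <- generate_dataset(shapes = c("C&E", "D&G"), n_per_shape = 10, seed = 1)
#' table(split_dataset(ds, seed = 1)$split)
split_dataset <- function(dataset, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-8 || length(ratios) != 3 || any(ratios < 0)) {
    abort("`ratios` must be three nonnegative fractions summing to 1.")
  }
  if (!"shape_label" %in% names(dataset)) {
    abort("`dataset` must have a `shape_label` column.")
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  split <- character(nrow(dataset))
  for (idx in split(seq_len(nrow(dataset)), dataset$shape_label)) {
    n <- length(idx)
    n_val <- floor(n * ratios[2])
    n_test <- floor(n * ratios[3])
    n_train <- n - n_val - n_test   # remainder goes to train
    lab <- c(rep("train", n_train), rep("validation", n_val),
             rep("test", n_test))
    split[idx] <- lab[sample.int(n)]
  }
  out <- dataset
  out$split <- factor(split, levels = c("train", "validation", "test"))
  out
}

# airPLS is scale-equivariant (z(c y) = c z(y)), so the optimal
# (lambda, tau) are scale-invariant; normalizing each spectrum to unit
# maximum before PCA removes the large between-family intensity-scale
# spread without losing any information relevant to the targets.
normalize_rows <- function(X) {
  mx <- apply(abs(X), 1, max)
  mx[mx == 0] <- 1
  X / mx
}

dataset_intensity_matrix <- function(dataset) {
  mats <- purrr::map(dataset$spectrum, ~.x$intensity)
  lens <- lengths(mats)
  if (length(unique(lens)) != 1) {
    abort("all spectra must share one wavenumber grid; resample first.")
  }
  do.call(rbind, mats)
}

#' Train a PCA + random-forest parameter predictor
#'
#' Learns a direct map from a raw spectrum to near-optimal airPLS
#' parameters: each spectrum is normalized to unit maximum (airPLS is
#' scale-equivariant, so the optimal parameters are scale-invariant),
#' projected onto the leading principal components of the training spectra
#' (smallest count explaining `pca_var` of the variance, capped at
#' `max_components`), and two `num_trees`-tree random-forest regressors
#' predict the parameters from the scores. Targets live in log space, and
#' the tau target is regressed as the residual around the log-log diagonal
#' line fitted to the training optima, so predictions land on the valley
#' where near-optimal pairs concentrate.
#'
#' When the labels carry `lambda_robust`/`tau_robust` columns (the
#' stability-preferring near-optima from [optimize_spectrum()]), those are
#' used as targets by default: the strict argmin often sits at the
#' fractured small-lambda end of the valley, where a regression model
#' cannot be accurate enough to be useful.
#'
#' @param train_data Nested dataset rows to train on (shared grid).
#' @param labels Tibble with `id` plus `lambda_star`/`tau_star` (and
#'   optionally `lambda_robust`/`tau_robust`) — grid-searched optima
#'   serving as regression targets.
#' @param pca_var Fraction of training variance the retained components
#'   must explain (default 0.995).
#' @param max_components Cap on retained components (default 50).
#' @param num_trees Trees per forest (default 100).
#' @param mtry Candidate features per split; `NULL` (default) uses all
#'   retained components, i.e. bagged trees — the configuration selected on
#'   validation-split PI during development.
#' @param nodesize Minimum terminal-node size (default 5).
#' @param target `"robust"` (default; falls back to the strict optima when
#'   robust columns are absent) or `"optimal"`.
#' @param seed Integer seed fixing the forest randomness.
#' @return A `param_predictor` object.
#' @export
train_param_predictor <- function(train_data, labels, pca_var = 0.995,
                                  max_components = 50L, num_trees = 100L,
                                  mtry = NULL, nodesize = 5L,
                                  target = c("robust", "optimal"),
                                  seed = 1L) {
  target <- match.arg(target)
  lab <- labels[match(train_data$id, labels$id), ]
  use_robust <- target == "robust" &&
    all(c("lambda_robust", "tau_robust") %in% names(lab))
  lam_t <- if (use_robust) lab$lambda_robust else lab$lambda_star
  tau_t <- if (use_robust) lab$tau_robust else lab$tau_star
  if (any(is.na(lam_t)) || any(is.na(tau_t))) {
    abort("every training spectrum needs a (lambda, tau) label.")
  }
  if (any(lam_t <= 0) || any(tau_t <= 0)) abort("labels must be positive.")
  X <- normalize_rows(dataset_intensity_matrix(train_data))
  if (nrow(X) < 2) abort("need at least 2 training spectra.")
  pca <- prcomp(X, center = TRUE, scale. = FALSE)
  cumvar <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- min(which(cumvar >= pca_var), max_components, ncol(pca$rotation))
  k <- max(k, 1L)
  scores <- pca$x[, seq_len(k), drop = FALSE]
  df <- as.data.frame(scores)
  y_lam <- log10(lam_t)
  # diagonal valley line of the training optima; tau is learned as the
  # residual around it (rotated target space)
  valley <- tryCatch(
    fit_parameter_region(tibble(lambda = lam_t, tau = tau_t)),
    error = function(e) list(slope = 0, intercept = mean(log10(tau_t))))
  y_tau <- log10(tau_t) - (valley$slope * y_lam + valley$intercept)
  if (is.null(mtry)) mtry <- k
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rf_lam <- randomForest::randomForest(x = df, y = y_lam, ntree = num_trees,
                                       mtry = mtry, nodesize = nodesize)
  rf_tau <- randomForest::randomForest(x = df, y = y_tau, ntree = num_trees,
                                       mtry = mtry, nodesize = nodesize)
  structure(
    list(rotation = pca$rotation[, seq_len(k), drop = FALSE],
         center = pca$center, n_components = k,
         forest_lambda = rf_lam, forest_tau = rf_tau,
         valley_slope = valley$slope, valley_intercept = valley$intercept,
         wavenumber = train_data$spectrum[[1]]$wavenumber,
         seed = seed, num_trees = num_trees, target = target,
         shapes = sort(unique(train_data$shape_label))),
    class = "param_predictor"
  )
}

#' @export
print.param_predictor <- function(x, ...) {
  cat("PCA + random-forest airPLS parameter predictor\n")
  cat(sprintf("  %d principal components; %d trees per target\n",
              x$n_components, x$num_trees))
  cat(sprintf("  trained on %d shape(s), grid of %d channels\n",
              length(x$shapes), length(x$wavenumber)))
  invisible(x)
}

#' Predict airPLS parameters for spectra
#'
#' Projects each spectrum onto the model's principal components and
#' returns the forests' back-transformed predictions. `tau` is clamped
#' into `(1e-12, 0.5)` so any downstream fit gets a valid tolerance.
#' Spectra on a different grid are resampled first (the model's grid must
#' lie inside theirs).
#'
#' @param model A `param_predictor`.
#' @param data A spectrum tibble, a nested dataset, or an intensity matrix
#'   (rows = spectra on the model grid).
#' @return A tibble with `lambda` and `tau` columns, one row per spectrum.
#' @export
predict_params <- function(model, data) {
  if (is.matrix(data)) {
    X <- data
  } else if (is.data.frame(data) && "spectrum" %in% names(data)) {
    specs <- purrr::map(data$spectrum, ~align_to_model(model, .x))
    X <- do.call(rbind, purrr::map(specs, ~.x$intensity))
  } else if (is.data.frame(data)) {
    sp <- align_to_model(model, as_spectrum(data))
    X <- matrix(sp$intensity, nrow = 1)
  } else {
    abort("`data` must be a spectrum, a nested dataset, or an intensity matrix.")
  }
  if (ncol(X) != length(model$wavenumber)) {
    abort("spectra are not on the model grid after resampling.")
  }
  X <- normalize_rows(X)
  scores <- sweep(X, 2, model$center) %*% model$rotation
  df <- as.data.frame(scores)
  colnames(df) <- colnames(model$rotation)
  log_lam <- predict(model$forest_lambda, df)
  log_tau <- predict(model$forest_tau, df) +
    model$valley_slope * log_lam + model$valley_intercept
  tibble(lambda = unname(10^log_lam),
         tau = pmin(pmax(unname(10^log_tau), 1e-12), 0.5))
}

align_to_model <- function(model, sp) {
  if (nrow(sp) == length(model$wavenumber) &&
      max(abs(sp$wavenumber - model$wavenumber)) < 1e-8 * diff(range(model$wavenumber))) {
    return(sp)
  }
  resample_to_grid(sp, model$wavenumber)
}

#' Flag outlier parameter predictions
#'
#' A prediction is an outlier when it degrades on the default-parameter
#' reference (`pi_ml < 0`) or its MAE exceeds ten times the grid-searched
#' optimum for the same spectrum.
#'
#' @param pi_ml PI of the predicted-parameter fit (percent).
#' @param mae_ml MAE of the predicted-parameter fit.
#' @param mae_op MAE at the grid-searched optimum.
#' @return Logical vector.
#' @export
is_outlier_prediction <- function(pi_ml, mae_ml, mae_op) {
  pi_ml < 0 | mae_ml > 10 * mae_op
}

#' Evaluate a parameter predictor on labeled spectra
#'
#' Fits an airPLS baseline (`p = 2`) at the predicted parameters for every
#' spectrum, computes `MAE_ML` against the true baseline, the
#' default-parameter reference `MAE_DP`, and `PI_ML`, and flags outlier
#' predictions. Spectra must carry true baselines; `labels` supplies the
#' grid-searched `mae_op` used by the outlier rule.
#'
#' @param model A `param_predictor`.
#' @param test_data Nested dataset rows to score.
#' @param labels Tibble with `id` and `mae_op` (e.g. [optimize_dataset()]
#'   output); optional — without it the MAE-ratio part of the outlier rule
#'   is skipped.
#' @return Per-spectrum tibble: `id`, `shape_label`, `lambda_hat`,
#'   `tau_hat`, `mae_ml`, `mae_dp`, `pi_ml`, `outlier`.
#' @export
evaluate_predictor <- function(model, test_data, labels = NULL) {
  if (nrow(test_data) == 0) {
    return(tibble(id = integer(), shape_label = character(),
                  lambda_hat = numeric(), tau_hat = numeric(),
                  mae_ml = numeric(), mae_dp = numeric(),
                  pi_ml = numeric(), outlier = logical()))
  }
  preds <- predict_params(model, test_data)
  rows <- purrr::pmap(
    list(test_data$id, test_data$shape_label, test_data$spectrum,
         preds$lambda, preds$tau),
    function(id, shape, sp, lam, tau) {
      check_spectrum(sp, need_truth = TRUE)
      fit <- airpls(sp, lambda = lam, tau = tau, p = 2L)
      dp <- airpls(sp, lambda = 100, tau = 1e-3, p = 1L)
      mae_ml <- mae(fit$data$baseline, sp$true_baseline)
      mae_dp <- mae(dp$data$baseline, sp$true_baseline)
      tibble(id = id, shape_label = shape, lambda_hat = lam, tau_hat = tau,
             mae_ml = mae_ml, mae_dp = mae_dp,
             pi_ml = percentage_improvement(mae_dp, mae_ml))
    })
  out <- dplyr::bind_rows(rows)
  if (!is.null(labels) && "mae_op" %in% names(labels)) {
    out <- dplyr::left_join(out, labels[, c("id", "mae_op")], by = "id")
    out$outlier <- is_outlier_prediction(out$pi_ml, out$mae_ml, out$mae_op)
  } else {
    out$outlier <- out$pi_ml < 0
  }
  out
}
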