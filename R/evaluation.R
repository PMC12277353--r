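#' Split samples into training and validation sets
#'
#' One seeded uniform split; the validation size is `ceiling(n * fraction)`
#' (4/5 - 1/5 at the default fraction). The same split is reused across the
#' whole order sweep by [run_experiment()], so order effects are not
#' confounded with split noise.
#'
#' @param n Number of samples (at least 5).
#' @param validation_fraction Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with sorted integer vectors `train` and `validation`
#'   (disjoint, exhaustive).
#' @export
split_train_validation <- function(n, validation_fraction = 0.2, seed = 1) {
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    abort_fracspec("validation_fraction must be in (0, 1).",
                   "fracspec_error_domain")
  }
  if (n < 5) {
    abort_fracspec("need at least 5 samples to split.",
                   "fracspec_error_validation")
  }
  set.seed(seed)
  n_val <- ceiling(n * validation_fraction)
  validation <- sort(sample(n, n_val))
  list(train = setdiff(seq_len(n), validation), validation = validation)
}

#' Regression accuracy metrics
#'
#' Coefficient of determination `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)`,
#' mean squared error and mean absolute error. For a constant truth vector,
#' R-squared is undefined and returned as `NA` with a warning; MSE and MAE
#' are still computed.
#'
#' @param y_true,y_pred Numeric vectors of equal length (at least 2).
#' @return One-row tibble with columns `r2`, `mse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    abort_fracspec("y_true and y_pred must have equal length >= 2.",
                   "fracspec_error_validation")
  }
  res <- y_true - y_pred
  r2 <- if (sd(y_true) == 0) {
    warn("y_true is constant: R-squared is undefined (NA).")
    NA_real_
  } else {
    r_squared(y_true, y_pred)
  }
  tibble(r2 = r2, mse = mean(res^2), mae = mean(abs(res)))
}

#' Configure a model-comparison experiment
#'
#' Bundles every tunable of [run_experiment()]: the order sweep, the model
#' list, the split fraction, the PLSR settings and the per-model regressor
#' specs (built from a grid preset, with optional per-model overrides).
#'
#' Model names: `"plsr"` (standalone PLSR with CV-selected components),
#' `"rf"`, `"xgb"`, `"mlp"` (standalone back ends on full spectra), and
#' `"plsr-rf"`, `"plsr-xgb"`, `"plsr-mlp"` (fusion models on latent scores
#' extracted by the cumulative-variance rule).
#'
#' @param orders Differentiation orders to sweep (default 0 to 3 by 0.1).
#' @param models Model names (default all seven).
#' @param validation_fraction Held-out fraction (default 0.2).
#' @param plsr_variance_threshold Cumulative predictor-variance threshold of
#'   the fusion extractor (default 0.75).
#' @param plsr_max_components Search range cap for standalone-PLSR component
#'   selection (default 20).
#' @param plsr_cap Component cap of the fusion extractor (default 30).
#' @param cv_folds Cross-validation folds for all tuning (default 10).
#' @param grid_preset Grid preset name passed to [regressor_spec()].
#' @param specs Optional named list of [regressor_spec()] overrides keyed by
#'   model name (e.g. `list(mlp = regressor_spec("feedforward_network", ...))`).
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(orders = seq(0, 3, by = 0.1),
                              models = c("plsr", "rf", "xgb", "mlp",
                                         "plsr-rf", "plsr-xgb", "plsr-mlp"),
                              validation_fraction = 0.2,
                              plsr_variance_threshold = 0.75,
                              plsr_max_components = 20,
                              plsr_cap = 30,
                              cv_folds = 10,
                              grid_preset = "default",
                              specs = NULL,
                              seed = 1) {
  known <- c("plsr", "rf", "xgb", "mlp", "plsr-rf", "plsr-xgb", "plsr-mlp")
  bad <- setdiff(models, known)
  if (length(bad)) {
    abort_fracspec(paste0("unknown model(s): ", paste(bad, collapse = ", ")),
                   "fracspec_error_config")
  }
  base_kind <- c(
    rf = "random_forest", xgb = "gradient_boosted_trees",
    mlp = "feedforward_network",
    `plsr-rf` = "random_forest", `plsr-xgb` = "gradient_boosted_trees",
    `plsr-mlp` = "feedforward_network"
  )
  all_specs <- list()
  for (m in setdiff(models, "plsr")) {
    all_specs[[m]] <- specs[[m]] %||%
      regressor_spec(base_kind[[m]], cv_folds = cv_folds, seed = seed,
                     preset = grid_preset)
  }
  structure(
    list(
      orders = orders, models = models,
      validation_fraction = validation_fraction,
      plsr_variance_threshold = plsr_variance_threshold,
      plsr_max_components = plsr_max_components,
      plsr_cap = plsr_cap,
      cv_folds = cv_folds,
      specs = all_specs,
      seed = as.integer(seed)
    ),
    class = "experiment_config"
  )
}

#' Run the full order-sweep x model-grid comparison
#'
#' The machinery behind the model-comparison table: one train/validation
#' split is fixed up front (before any transform); for each differentiation
#' order the spectra are transformed once and every requested model is fitted
#' on the transformed training rows (latent extraction, grid search and refit
#' touch training rows only) and scored on both splits. Individual cell
#' failures are recorded in the `error` column and the run continues. Fully
#' reproducible given the config seed.
#'
#' @param data A [spectra_set()] at order 0.
#' @param config An [experiment_config()].
#' @return A `comparison_tbl` tibble with one row per (model, order, split)
#'   and columns `model, order, split, r2, mse, mae, n_components,
#'   hyperparams, seed, error`; the split indices are attached as attribute
#'   `"split"`.
#' @export
run_experiment <- function(data, config = experiment_config()) {
  check_spectra_set(data)
  stopifnot(inherits(config, "experiment_config"))
  if (spectra_order(data) != 0) {
    abort_fracspec("run_experiment() requires raw (order 0) spectra.",
                   "fracspec_error_state")
  }
  split <- split_train_validation(nrow(data), config$validation_fraction,
                                  seed = config$seed)
  rows <- list()
  for (oi in seq_along(config$orders)) {
    v <- config$orders[oi]
    ts <- transform_set(data, v)
    s_train <- slice_samples(ts, split$train)
    s_val <- slice_samples(ts, split$validation)
    for (mi in seq_along(config$models)) {
      model_name <- config$models[mi]
      cell_seed <- derive_seed(config$seed, mi, round(v * 10))
      cell <- tryCatch(
        fit_and_score_cell(model_name, s_train, s_val, config, cell_seed),
        error = function(e) {
          tibble(
            model = model_name, order = v,
            split = c("train", "validation"),
            r2 = NA_real_, mse = NA_real_, mae = NA_real_,
            n_components = NA_integer_, hyperparams = NA_character_,
            seed = cell_seed, error = conditionMessage(e)
          )
        }
      )
      cell$order <- v
      rows[[length(rows) + 1]] <- cell
    }
  }
  out <- list_rbind(rows)
  class(out) <- c("comparison_tbl", class(out))
  attr(out, "split") <- split
  attr(out, "seed") <- config$seed
  out
}

fit_and_score_cell <- function(model_name, s_train, s_val, config, cell_seed) {
  y_train <- s_train$potassium
  y_val <- s_val$potassium
  if (model_name == "plsr") {
    X_train <- spectra_matrix(s_train)
    k <- suppressWarnings(select_components_cv(
      X_train, y_train,
      max_components = config$plsr_max_components,
      folds = config$cv_folds, seed = cell_seed
    ))
    fit <- suppressWarnings(fit_plsr(X_train, y_train, k))
    pred_train <- predict(fit, X_train)
    pred_val <- predict(fit, spectra_matrix(s_val))
    n_comp <- fit$n_components
    hyper <- format_params(list(n_components = n_comp))
  } else {
    use_plsr <- startsWith(model_name, "plsr-")
    spec <- config$specs[[model_name]]
    spec$seed <- cell_seed
    fit <- suppressWarnings(fit_fusion(
      s_train, spec$kind, use_plsr = use_plsr,
      threshold = config$plsr_variance_threshold, spec = spec,
      cap = config$plsr_cap
    ))
    pred_train <- predict(fit, s_train)
    pred_val <- predict(fit, s_val)
    n_comp <- if (use_plsr) fit$extractor$n_components else NA_integer_
    hyper <- format_params(fit$regressor$chosen)
  }
  bind_rows(
    mutate(regression_metrics(y_train, pred_train), split = "train"),
    mutate(regression_metrics(y_val, pred_val), split = "validation")
  ) |>
    mutate(
      model = model_name,
      order = NA_real_, # filled by the caller
      n_components = as.integer(n_comp),
      hyperparams = hyper,
      seed = cell_seed,
      error = NA_character_
    ) |>
    select("model", "order", "split", "r2", "mse", "mae",
           "n_components", "hyperparams", "seed", "error")
}

#' Select each model's best differentiation order
#'
#' Per model, the order maximising validation R-squared (the selection
#' criterion used throughout; MSE/MAE are reported, not ranked on). Ties are
#' broken toward the lower order; error-marked cells are excluded. Models
#' whose cells all failed are dropped with a warning.
#'
#' @param table A `comparison_tbl` from [run_experiment()].
#' @return Tibble with one row per model: `model, order, r2, mse, mae,
#'   n_components`.
#' @export
select_best <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort_fracspec("comparison table must be non-empty.",
                   "fracspec_error_validation")
  }
  usable <- filter(table, .data$split == "validation", is.na(.data$error),
                   !is.na(.data$r2))
  dropped <- setdiff(unique(table$model), unique(usable$model))
  if (length(dropped)) {
    warn(paste0("no usable cells for model(s): ",
                paste(dropped, collapse = ", ")))
  }
  usable |>
    group_by(.data$model) |>
    arrange(dplyr::desc(.data$r2), .data$order, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select("model", "order", "r2", "mse", "mae", "n_components")
}
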