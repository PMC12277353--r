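#' Specify a tunable base regressor
#'
#' Describes one of the three machine-learning back ends and its
#' hyperparameter grid for seeded grid-search tuning with K-fold
#' cross-validation.
#'
#' Grid presets (`"default"` unions the two tree-count schedules reported for
#' the random forest; `"reduced"` is a small grid for quick experiments):
#' * `random_forest` (via \pkg{ranger}): `num.trees` 50/100/150/200/300,
#'   `max.depth` 5/10/15, `mtry` `"sqrt"`/`"log2"`/`"10"`.
#' * `gradient_boosted_trees` (via \pkg{xgboost}): `learning_rate`
#'   0.01/0.05/0.1, `max_depth` 3/5/7, `n_estimators` 100/200/300.
#' * `feedforward_network` (via \pkg{nnet}; single hidden layer, logistic
#'   activation, BFGS optimisation, inputs and response standardised by
#'   training statistics): `hidden_size` 100/50, `alpha` (L2 weight decay)
#'   1e-4/1e-3/1e-2.
#'
#' @param kind One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"feedforward_network"`.
#' @param grid Named list of candidate vectors; `NULL` uses the preset grid.
#' @param cv_folds Cross-validation folds for tuning (default 10).
#' @param seed Integer seed controlling fold assignment and every stochastic
#'   fit.
#' @param preset `"default"`, `"paper_initial"` (trees 50-200 in steps of
#'   50), `"paper_grid"` (trees 100/200/300) or `"reduced"`.
#' @param maxit Maximum optimiser iterations for the feed-forward network.
#' @return A `regressor_spec`.
#' @export
regressor_spec <- function(kind = c("random_forest", "gradient_boosted_trees",
                                    "feedforward_network"),
                           grid = NULL, cv_folds = 10, seed = 1,
                           preset = c("default", "paper_initial",
                                      "paper_grid", "reduced"),
                           maxit = 2000) {
  kind <- match.arg(kind)
  preset <- match.arg(preset)
  grid <- grid %||% default_grid(kind, preset)
  validate_grid(kind, grid)
  structure(
    list(kind = kind, grid = grid, cv_folds = as.integer(cv_folds),
         seed = as.integer(seed), maxit = as.integer(maxit)),
    class = "regressor_spec"
  )
}

default_grid <- function(kind, preset = "default") {
  switch(kind,
    random_forest = switch(preset,
      default = list(num.trees = c(50, 100, 150, 200, 300),
                     max.depth = c(5, 10, 15),
                     mtry = c("sqrt", "log2", "10")),
      paper_initial = list(num.trees = c(50, 100, 150, 200),
                           max.depth = c(5, 10, 15),
                           mtry = c("sqrt", "log2", "10")),
      paper_grid = list(num.trees = c(100, 200, 300),
                        max.depth = c(5, 10, 15),
                        mtry = c("sqrt", "log2", "10")),
      reduced = list(num.trees = 200, max.depth = c(10, 15),
                     mtry = c("sqrt", "10"))
    ),
    gradient_boosted_trees = switch(preset,
      default = list(learning_rate = c(0.01, 0.05, 0.1),
                     max_depth = c(3, 5, 7),
                     n_estimators = c(100, 200, 300)),
      paper_initial = ,
      paper_grid = list(learning_rate = c(0.01, 0.05, 0.1),
                        max_depth = c(3, 5, 7),
                        n_estimators = c(100, 200, 300)),
      reduced = list(learning_rate = c(0.05, 0.1), max_depth = 3,
                     n_estimators = 100)
    ),
    feedforward_network = switch(preset,
      default = ,
      paper_initial = ,
      paper_grid = list(hidden_size = c(100, 50),
                        alpha = c(1e-4, 1e-3, 1e-2)),
      reduced = list(hidden_size = 16, alpha = c(1e-3, 1e-2))
    )
  )
}

grid_params <- list(
  random_forest = c("num.trees", "max.depth", "mtry"),
  gradient_boosted_trees = c("learning_rate", "max_depth", "n_estimators"),
  feedforward_network = c("hidden_size", "alpha")
)

validate_grid <- function(kind, grid) {
  if (length(grid) == 0 || any(lengths(grid) == 0)) {
    abort_fracspec("hyperparameter grid must be non-empty.",
                   "fracspec_error_config")
  }
  unknown <- setdiff(names(grid), grid_params[[kind]])
  if (length(unknown)) {
    abort_fracspec(
      paste0("unknown hyperparameter(s) for ", kind, ": ",
             paste(unknown, collapse = ", ")),
      "fracspec_error_config"
    )
  }
  invisible(TRUE)
}

resolve_mtry <- function(mtry, p) {
  if (is.character(mtry)) {
    mtry <- switch(mtry,
      sqrt = floor(sqrt(p)),
      log2 = floor(log2(p)),
      suppressWarnings(as.numeric(mtry))
    )
  }
  if (is.na(mtry) || mtry < 1) {
    abort_fracspec("invalid mtry candidate.", "fracspec_error_config")
  }
  as.integer(min(mtry, p))
}

# adapters around the delegated implementations -------------------------------

fit_base_regressor <- function(kind, params, X, y, seed, maxit = 2000) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  switch(kind,
    random_forest = {
      fit <- ranger::ranger(
        x = X, y = y,
        num.trees = as.integer(params$num.trees),
        max.depth = as.integer(params$max.depth %||% 0),
        mtry = resolve_mtry(params$mtry %||% "sqrt", ncol(X)),
        seed = seed, num.threads = 1
      )
      structure(list(fit = fit, features = colnames(X)), class = "fracspec_rf")
    },
    gradient_boosted_trees = {
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(
          eta = params$learning_rate %||% 0.1,
          max_depth = as.integer(params$max_depth %||% 3),
          objective = "reg:squarederror",
          nthread = 1
        ),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = as.integer(params$n_estimators %||% 100),
        verbose = 0
      )
      structure(list(fit = fit, features = colnames(X)), class = "fracspec_gbt")
    },
    feedforward_network = {
      xm <- colMeans(X)
      xs <- apply(X, 2, sd)
      xs[xs == 0] <- 1
      ym <- mean(y)
      ys <- sd(y)
      if (ys == 0) ys <- 1
      set.seed(seed)
      fit <- nnet::nnet(
        x = sweep(sweep(X, 2, xm), 2, xs, "/"),
        y = (y - ym) / ys,
        size = as.integer(params$hidden_size %||% 100),
        decay = params$alpha %||% 1e-4,
        linout = TRUE, maxit = maxit, trace = FALSE, MaxNWts = 1e6
      )
      structure(list(fit = fit, features = colnames(X),
                     xm = xm, xs = xs, ym = ym, ys = ys),
                class = "fracspec_ffn")
    }
  )
}

predict_base_regressor <- function(object, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (inherits(object, "fracspec_rf")) {
    predict(object$fit, data = X, num.threads = 1)$predictions
  } else if (inherits(object, "fracspec_gbt")) {
    predict(object$fit, newdata = xgboost::xgb.DMatrix(X))
  } else if (inherits(object, "fracspec_ffn")) {
    z <- sweep(sweep(X, 2, object$xm), 2, object$xs, "/")
    as.vector(predict(object$fit, z)) * object$ys + object$ym
  } else {
    abort_fracspec("unknown base regressor.", "fracspec_error_state")
  }
}

# -----------------------------------------------------------------------------

#' Grid-search tune and fit a base regressor
#'
#' Exhaustive grid search maximising mean K-fold cross-validated R-squared
#' (each held-out fold scored against its own mean), followed by a refit on
#' all provided rows. Ties are broken by grid enumeration order (the first
#' grid dimension varies fastest). Deterministic given the spec's seed. A
#' single-cell grid skips cross-validation.
#'
#' @param spec A [regressor_spec()].
#' @param X Feature matrix (latent scores or full spectra).
#' @param y Response vector.
#' @return A `tuned_regressor`: fitted back end, `chosen` hyperparameters,
#'   and the per-cell `cv_results` tibble.
#' @export
tune_and_fit <- function(spec, X, y) {
  stopifnot(inherits(spec, "regressor_spec"))
  X <- as.matrix(X)
  n <- nrow(X)
  if (sd(y) == 0) {
    abort_fracspec("response is constant; tuning R-squared is undefined.",
                   "fracspec_error_degenerate")
  }
  cells <- expand.grid(spec$grid, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) > 1) {
    if (n < spec$cv_folds) {
      abort_fracspec("need at least one sample per cross-validation fold.",
                     "fracspec_error_validation")
    }
    set.seed(spec$seed)
    fold_id <- sample(rep(seq_len(spec$cv_folds), length.out = n))
    cv_r2 <- vapply(seq_len(nrow(cells)), function(ci) {
      params <- as.list(cells[ci, , drop = FALSE])
      mean(vapply(seq_len(spec$cv_folds), function(f) {
        tr <- fold_id != f
        fit <- fit_base_regressor(
          spec$kind, params, X[tr, , drop = FALSE], y[tr],
          seed = derive_seed(spec$seed, ci, f), maxit = spec$maxit
        )
        r_squared(y[!tr], predict_base_regressor(fit, X[!tr, , drop = FALSE]))
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(cv_r2)
  } else {
    cv_r2 <- NA_real_
    best <- 1L
  }
  chosen <- as.list(cells[best, , drop = FALSE])
  fit <- fit_base_regressor(spec$kind, chosen, X, y,
                            seed = spec$seed, maxit = spec$maxit)
  structure(
    list(
      kind = spec$kind,
      fit = fit,
      chosen = chosen,
      cv_results = mutate(as_tibble(cells), mean_cv_r2 = cv_r2),
      n_features = ncol(X),
      spec = spec
    ),
    class = "tuned_regressor"
  )
}

derive_seed <- function(seed, cell, fold = 0) {
  as.integer((as.numeric(seed) + 7919 * cell + 104729 * fold) %% 2147483647)
}

#' @export
predict.tuned_regressor <- function(object, newdata, ...) {
  predict_base_regressor(object$fit, newdata)
}

#' @export
print.tuned_regressor <- function(x, ...) {
  cat(sprintf("# tuned %s (%d feature(s)); chosen: %s\n",
              x$kind, x$n_features, format_params(x$chosen)))
  invisible(x)
}

format_params <- function(p) {
  paste(names(p), vapply(p, function(v) format(v, digits = 6), character(1)),
        sep = "=", collapse = ";")
}

#' Fit a PLSR-fusion (or standalone) potassium model
#'
#' With `use_plsr = TRUE` (the fusion construction), latent variables are
#' extracted from the training spectra by the cumulative explained-variance
#' rule and the tuned base regressor is fitted on the scores; with
#' `use_plsr = FALSE` the regressor is fitted on the full spectra (standalone
#' baseline). The training differentiation order is recorded and enforced at
#' prediction time.
#'
#' @param train A [spectra_set()] at a single differentiation order (the
#'   training rows only; validation rows must not be passed here).
#' @param kind Base regressor kind, as in [regressor_spec()].
#' @param use_plsr If `TRUE`, chain the PLSR latent extractor in front of the
#'   regressor.
#' @param threshold Cumulative predictor-variance threshold of the extractor
#'   (default 0.75).
#' @param spec A [regressor_spec()]; defaults to `regressor_spec(kind)`.
#' @param cap Component cap of the extractor (default 30).
#' @return A `fusion_model`.
#' @export
fit_fusion <- function(train, kind, use_plsr = TRUE, threshold = 0.75,
                       spec = NULL, cap = 30) {
  check_spectra_set(train)
  spec <- spec %||% regressor_spec(kind)
  stopifnot(identical(spec$kind, kind))
  X <- spectra_matrix(train)
  y <- train$potassium
  extractor <- NULL
  if (use_plsr) {
    ex <- extract_latents_by_variance(X, y, threshold = threshold, cap = cap)
    extractor <- ex$model
    features <- ex$scores
  } else {
    features <- X
  }
  regressor <- tune_and_fit(spec, features, y)
  structure(
    list(
      extractor = extractor,
      regressor = regressor,
      kind = kind,
      use_plsr = use_plsr,
      threshold = if (use_plsr) threshold else NA_real_,
      order = spectra_order(train),
      wavelengths = spectra_wavelengths(train),
      n_features = ncol(features)
    ),
    class = "fusion_model"
  )
}

#' @export
predict.fusion_model <- function(object, newdata, ...) {
  check_spectra_set(newdata)
  if (!isTRUE(all.equal(spectra_order(newdata), object$order))) {
    abort_fracspec(
      sprintf("model was trained at differentiation order %g but data is at order %g.",
              object$order, spectra_order(newdata)),
      "fracspec_error_state"
    )
  }
  if (!identical(spectra_wavelengths(newdata), object$wavelengths)) {
    abort_fracspec("wavelength grid of the data does not match the model.",
                   "fracspec_error_alignment")
  }
  X <- spectra_matrix(newdata)
  features <- if (object$use_plsr) plsr_scores(object$extractor, X) else X
  predict(object$regressor, features)
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(
    "# %s%s at differentiation order %g; regressor input width %d\n",
    if (x$use_plsr) "PLSR-" else "standalone ", x$kind, x$order, x$n_features
  ))
  invisible(x)
}
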