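#' Band-wise Pearson correlation with potassium
#'
#' Pearson correlation between each reflectance band and the response,
#' computed by the explicit two-pass formula. Bands with zero variance are
#' reported as `NA` (undefined) rather than 0.
#'
#' @param X Reflectance matrix (samples x bands) or a [spectra_set()], in
#'   which case the response defaults to its potassium column.
#' @param y Response vector; ignored (may be `NULL`) when `X` is a
#'   [spectra_set()].
#' @return A tibble with columns `wavelength` (band index when `X` is a bare
#'   matrix without wavelength names) and `r`.
#' @export
bandwise_correlation <- function(X, y = NULL) {
  if (inherits(X, "spectra_set")) {
    y <- y %||% X$potassium
    wl <- spectra_wavelengths(X)
    X <- spectra_matrix(X)
  } else {
    X <- as.matrix(X)
    wl <- suppressWarnings(as.numeric(colnames(X)))
    if (length(wl) == 0 || anyNA(wl)) wl <- seq_len(ncol(X))
  }
  if (nrow(X) < 3) {
    abort_fracspec("need at least 3 samples for a correlation.",
                   "fracspec_error_validation")
  }
  if (sd(y) == 0) {
    abort_fracspec("response is constant; correlation undefined.",
                   "fracspec_error_degenerate")
  }
  tibble(wavelength = wl, r = pearson_columns(X, y))
}

# two-pass Pearson per column; zero-variance columns -> NA
pearson_columns <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X)
  ym <- mean(y)
  yc <- y - ym
  Xc <- sweep(X, 2, xm)
  sx <- sqrt(colSums(Xc^2))
  sy <- sqrt(sum(yc^2))
  r <- unname(as.vector(crossprod(Xc, yc)) / (sx * sy))
  r[sx == 0] <- NA_real_
  r
}

#' Correlation surface over a differentiation-order sweep
#'
#' Absolute band-potassium Pearson correlations per (order, band), the
#' per-order maximum, and the order at which the overall maximum occurs.
#' Zero-variance (undefined) bands are excluded from the per-order maxima.
#'
#' @param sweep Named list of [spectra_set()]s, as returned by
#'   [sweep_orders()]; all entries must share wavelengths and sample order.
#' @param y Response vector; defaults to the potassium column of the first
#'   entry.
#' @return A `correlation_surface` object: list with `surface` (long tibble
#'   `order, wavelength, abs_r`), `per_order_max` (tibble `order, max_abs_r,
#'   wavelength`) and `best_order`.
#' @export
correlation_surface <- function(sweep, y = NULL) {
  if (length(sweep) == 0) {
    abort_fracspec("sweep must be non-empty.", "fracspec_error_validation")
  }
  wl0 <- spectra_wavelengths(sweep[[1]])
  ids0 <- sweep[[1]]$sample_id
  for (s in sweep) {
    if (!identical(spectra_wavelengths(s), wl0) ||
        !identical(s$sample_id, ids0)) {
      abort_fracspec(
        "all sweep entries must share the same wavelengths and sample order.",
        "fracspec_error_alignment"
      )
    }
  }
  y <- y %||% sweep[[1]]$potassium
  orders <- vapply(sweep, spectra_order, numeric(1))
  surface <- imap(sweep, function(s, nm) {
    tibble(
      order = spectra_order(s),
      wavelength = wl0,
      abs_r = abs(pearson_columns(spectra_matrix(s), y))
    )
  }) |> list_rbind()
  per_order_max <- surface |>
    filter(!is.na(.data$abs_r)) |>
    group_by(.data$order) |>
    summarise(
      max_abs_r = max(.data$abs_r),
      wavelength = .data$wavelength[which.max(.data$abs_r)],
      .groups = "drop"
    )
  best <- per_order_max$order[which.max(per_order_max$max_abs_r)]
  structure(
    list(surface = surface, per_order_max = per_order_max, best_order = best),
    class = "correlation_surface"
  )
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf(
    "# correlation surface: %d orders x %d bands; max |r| = %.3f at order %.1f\n",
    nrow(x$per_order_max), length(unique(x$surface$wavelength)),
    max(x$per_order_max$max_abs_r), x$best_order
  ))
  print(x$per_order_max)
  invisible(x)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Sequential latent-variable extraction: each component's weight vector is
#' proportional to the residual cross-covariance `X'y` on centred data; the
#' score is the projection of the residual predictors on that direction, and
#' both `X` and `y` are deflated before the next component. Predictions are
#' `y_mean + sum_m f_m a_m` with `f` the latent scores and `a` the per-latent
#' regression coefficients.
#'
#' @param X Predictor matrix (samples x bands), no missing values.
#' @param y Response vector.
#' @param n_components Number of latent variables; at most
#'   `min(n_samples - 1, n_bands)`. Extraction stops early (with the actual
#'   count recorded) if the residual cross-covariance vanishes.
#' @param scale If `TRUE`, predictor columns are scaled to unit variance
#'   (default `FALSE`: differentiated spectra carry meaningful relative
#'   magnitudes).
#' @return A `plsr_model`: weights `x_weights`, loadings `x_loadings`,
#'   per-latent coefficients `coefficients`, centring constants, per-component
#'   and cumulative fractions of predictor variance explained, training
#'   scores, and the rotation used to project new spectra.
#' @export
fit_plsr <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (anyNA(X) || anyNA(y)) {
    abort_fracspec("X and y must not contain missing values.",
                   "fracspec_error_validation")
  }
  max_rank <- min(n - 1, p)
  if (n_components < 1 || n_components > max_rank) {
    abort_fracspec(
      sprintf("n_components must be in [1, %d] for %d samples x %d bands.",
              max_rank, n, p),
      "fracspec_error_rank"
    )
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  x_sd <- NULL
  if (scale) {
    x_sd <- apply(Xc, 2, sd)
    x_sd[x_sd == 0] <- 1
    Xc <- sweep(Xc, 2, x_sd, "/")
  }
  yc <- y - y_mean
  ss_x <- sum(Xc^2)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  scores <- matrix(0, n, n_components)
  a <- numeric(n_components)
  x_var <- numeric(n_components)
  fitted_m <- 0
  for (m in seq_len(n_components)) {
    w <- as.vector(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, abs(y_mean)) || !is.finite(nw) || nw == 0) break
    w <- w / nw
    f <- as.vector(Xc %*% w)
    f2 <- sum(f^2)
    if (f2 < .Machine$double.eps) break
    pl <- as.vector(crossprod(Xc, f)) / f2
    am <- sum(yc * f) / f2
    Xc <- Xc - tcrossprod(f, pl)
    yc <- yc - am * f
    W[, m] <- w
    P[, m] <- pl
    scores[, m] <- f
    a[m] <- am
    x_var[m] <- f2 * sum(pl^2) / ss_x
    fitted_m <- m
  }
  if (fitted_m == 0) {
    abort_fracspec("zero cross-covariance between X and y; no component can be extracted.",
                   "fracspec_error_degenerate")
  }
  early <- fitted_m < n_components
  if (early) {
    warn(sprintf(
      "residual cross-covariance vanished: %d of %d requested components extracted.",
      fitted_m, n_components
    ))
  }
  idx <- seq_len(fitted_m)
  model <- structure(
    list(
      n_components = fitted_m,
      requested_components = n_components,
      early_stopped = early,
      x_weights = W[, idx, drop = FALSE],
      x_loadings = P[, idx, drop = FALSE],
      coefficients = a[idx],
      x_mean = x_mean,
      y_mean = y_mean,
      x_sd = x_sd,
      x_variance = x_var[idx],
      cum_x_variance = cumsum(x_var[idx]),
      scores = scores[, idx, drop = FALSE],
      nobs = n
    ),
    class = "plsr_model"
  )
  model$rotation <- plsr_rotation(model)
  model
}

# R = W (P'W)^{-1}: maps centred spectra to scores; also used to assemble the
# full-spectrum coefficient vector B = R a.
plsr_rotation <- function(model) {
  model$x_weights %*%
    solve(crossprod(model$x_loadings, model$x_weights))
}

truncate_plsr <- function(model, m) {
  if (m >= model$n_components) return(model)
  idx <- seq_len(m)
  model$n_components <- m
  model$x_weights <- model$x_weights[, idx, drop = FALSE]
  model$x_loadings <- model$x_loadings[, idx, drop = FALSE]
  model$coefficients <- model$coefficients[idx]
  model$x_variance <- model$x_variance[idx]
  model$cum_x_variance <- model$cum_x_variance[idx]
  model$scores <- model$scores[, idx, drop = FALSE]
  model$rotation <- plsr_rotation(model)
  model
}

#' Project spectra onto the latent variables of a fitted PLSR model
#'
#' Applies the training centring (and scaling, if any) and the stored
#' rotation; projecting the training matrix reproduces the stored training
#' scores.
#'
#' @param model A `plsr_model`.
#' @param X New predictor matrix with the same bands as the training data.
#' @param ncomp Number of leading components to return (default: all).
#' @return Scores matrix (samples x components), columns `lv1`, `lv2`, ...
#' @export
plsr_scores <- function(model, X, ncomp = NULL) {
  stopifnot(inherits(model, "plsr_model"))
  ncomp <- ncomp %||% model$n_components
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) {
    abort_fracspec("new data has a different number of bands than the model.",
                   "fracspec_error_alignment")
  }
  Xc <- sweep(X, 2, model$x_mean)
  if (!is.null(model$x_sd)) Xc <- sweep(Xc, 2, model$x_sd, "/")
  s <- Xc %*% model$rotation[, seq_len(ncomp), drop = FALSE]
  colnames(s) <- paste0("lv", seq_len(ncomp))
  s
}

#' @export
predict.plsr_model <- function(object, newdata, ncomp = NULL, ...) {
  ncomp <- ncomp %||% object$n_components
  s <- plsr_scores(object, newdata, ncomp = ncomp)
  as.vector(object$y_mean + s %*% object$coefficients[seq_len(ncomp)])
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf(
    "# PLS1 (NIPALS): %d component(s), %.1f%% predictor variance explained\n",
    x$n_components, 100 * x$cum_x_variance[x$n_components]
  ))
  invisible(x)
}

#' Choose the number of PLSR components by cross-validation
#'
#' Exhaustive search over `1:max_components`, scored by mean cross-validated
#' R-squared (each held-out fold scored against its own mean); ties are broken
#' toward fewer components. Fold assignment is a seeded shuffle, so the choice
#' is deterministic given the seed.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param max_components Upper end of the searched range (default 20); shrunk
#'   with a warning if the training folds cannot support it.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return The selected component count, with the per-count mean CV R-squared
#'   attached as attribute `"cv_r2"`.
#' @export
select_components_cv <- function(X, y, max_components = 20, folds = 10,
                                 seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (max_components < 1) {
    abort_fracspec("max_components must be >= 1.", "fracspec_error_domain")
  }
  if (folds < 2 || n < folds) {
    abort_fracspec("need folds >= 2 and at least one sample per fold.",
                   "fracspec_error_domain")
  }
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  feasible <- min(max_components, n - max(table(fold_id)) - 1, ncol(X))
  if (feasible < max_components) {
    warn(sprintf("searched range shrunk to 1..%d by the training-fold rank limit.",
                 feasible))
  }
  r2 <- matrix(NA_real_, folds, feasible)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    model <- fit_plsr(X[tr, , drop = FALSE], y[tr], feasible)
    for (m in seq_len(min(feasible, model$n_components))) {
      pred <- predict(model, X[!tr, , drop = FALSE], ncomp = m)
      r2[f, m] <- r_squared(y[!tr], pred)
    }
  }
  mean_r2 <- colMeans(r2)
  mean_r2[is.na(mean_r2)] <- -Inf # counts no fold could fit
  best <- which.max(mean_r2) # first maximum: ties go to fewer components
  structure(as.integer(best), cv_r2 = mean_r2)
}

r_squared <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

#' Extract latent variables by the cumulative explained-variance rule
#'
#' Fits PLSR components sequentially and stops at the first component count
#' whose cumulative explained predictor variance reaches `threshold`
#' (default 75%), or at `cap` components if the threshold is out of reach
#' (recorded with a warning). At least one component is always extracted.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param threshold Cumulative predictor-variance fraction in (0, 1\].
#' @param cap Maximum number of components (default 30).
#' @return List with `scores` (training scores, samples x m), `model` (the
#'   truncated `plsr_model`) and `threshold_reached` (logical).
#' @export
extract_latents_by_variance <- function(X, y, threshold = 0.75, cap = 30) {
  if (threshold <= 0 || threshold > 1) {
    abort_fracspec("threshold must be in (0, 1].", "fracspec_error_domain")
  }
  if (cap < 1) {
    abort_fracspec("cap must be >= 1.", "fracspec_error_domain")
  }
  X <- as.matrix(X)
  cap <- min(cap, nrow(X) - 1, ncol(X))
  model <- suppressWarnings(fit_plsr(X, y, cap))
  hit <- which(model$cum_x_variance >= threshold)
  reached <- length(hit) > 0
  m <- if (reached) hit[1] else model$n_components
  if (!reached) {
    warn(sprintf(
      "cumulative explained variance %.1f%% below the %.0f%% threshold at the %d-component cap.",
      100 * model$cum_x_variance[model$n_components], 100 * threshold, cap
    ))
  }
  model <- truncate_plsr(model, m)
  scores <- model$scores
  colnames(scores) <- paste0("lv", seq_len(ncol(scores)))
  list(scores = scores, model = model, threshold_reached = reached)
}
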