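#' Tidy a fitted PLS1 model
#'
#' One row per latent variable with its regression coefficient and the
#' per-component and cumulative fractions of predictor variance explained.
#'
#' @param x A `plsr_model`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `coefficient`, `x_variance`,
#'   `cum_x_variance`.
#' @export
#' @exportS3Method generics::tidy
tidy.plsr_model <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    coefficient = x$coefficients,
    x_variance = x$x_variance,
    cum_x_variance = x$cum_x_variance
  )
}

#' @rdname tidy.plsr_model
#' @export
#' @exportS3Method generics::glance
glance.plsr_model <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    requested_components = x$requested_components,
    early_stopped = x$early_stopped,
    cum_x_variance = x$cum_x_variance[x$n_components],
    nobs = x$nobs
  )
}

#' Tidy a tuned base regressor
#'
#' The grid-search table: one row per hyperparameter cell with its mean
#' cross-validated R-squared.
#'
#' @param x A `tuned_regressor`.
#' @param ... Unused.
#' @return `tidy()`: the `cv_results` tibble. `glance()`: a one-row tibble
#'   with the chosen hyperparameters and feature count.
#' @export
#' @exportS3Method generics::tidy
tidy.tuned_regressor <- function(x, ...) {
  x$cv_results
}

#' @rdname tidy.tuned_regressor
#' @export
#' @exportS3Method generics::glance
glance.tuned_regressor <- function(x, ...) {
  mutate(as_tibble(x$chosen), kind = x$kind, n_features = x$n_features)
}

#' Tidy a fusion model
#'
#' @param x A `fusion_model`.
#' @param ... Unused.
#' @return `tidy()`: the extractor's component table (empty for standalone
#'   models). `glance()`: one row with kind, differentiation order, extractor
#'   width and chosen hyperparameters.
#' @export
#' @exportS3Method generics::tidy
tidy.fusion_model <- function(x, ...) {
  if (is.null(x$extractor)) {
    return(tibble(component = integer(), coefficient = double(),
                  x_variance = double(), cum_x_variance = double()))
  }
  tidy(x$extractor)
}

#' @rdname tidy.fusion_model
#' @export
#' @exportS3Method generics::glance
glance.fusion_model <- function(x, ...) {
  tibble(
    kind = x$kind,
    fusion = x$use_plsr,
    order = x$order,
    n_features = x$n_features,
    n_components = if (x$use_plsr) x$extractor$n_components else NA_integer_,
    hyperparams = format_params(x$regressor$chosen)
  )
}

#' Tidy a correlation surface
#'
#' @param x A `correlation_surface`.
#' @param ... Unused.
#' @return `tidy()`: the long (order, wavelength, abs_r) tibble. `glance()`:
#'   one row with the best order and its maximum absolute correlation.
#' @export
#' @exportS3Method generics::tidy
tidy.correlation_surface <- function(x, ...) {
  x$surface
}

#' @rdname tidy.correlation_surface
#' @export
#' @exportS3Method generics::glance
glance.correlation_surface <- function(x, ...) {
  best <- filter(x$per_order_max, .data$order == x$best_order)
  tibble(
    best_order = x$best_order,
    max_abs_r = best$max_abs_r[1],
    wavelength = best$wavelength[1],
    n_orders = nrow(x$per_order_max)
  )
}
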