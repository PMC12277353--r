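#' Grunwald-Letnikov weight sequence
#'
#' Generalised binomial weights `w_m = (-1)^m Gamma(v+1) / (m! Gamma(v-m+1))`
#' defining the discrete fractional-derivative operator of order `v` at unit
#' step. Computed by the pole-safe multiplicative recursion
#' `w_0 = 1; w_m = w_{m-1} * (m - 1 - v) / m`, which agrees with the direct
#' Gamma-ratio form wherever the Gamma arguments avoid poles and yields exact
#' zeros beyond the binomial truncation at integer orders.
#'
#' @param order Differentiation order `v >= 0`.
#' @param length Number of weights (history points) to return.
#' @return A `gl_weights` object: list with `order`, `h` (step size, fixed at
#'   1 band) and `weights` (numeric vector of length `length`).
#' @export
gl_weights <- function(order, length) {
  if (!is.numeric(order) || length(order) != 1 || is.na(order) || order < 0) {
    abort_fracspec("differentiation order must be a single number >= 0.",
                   "fracspec_error_domain")
  }
  if (length < 1) {
    abort_fracspec("length must be >= 1.", "fracspec_error_domain")
  }
  w <- numeric(length)
  w[1] <- 1
  if (length > 1) {
    for (m in seq_len(length - 1)) {
      w[m + 1] <- w[m] * (m - 1 - order) / m
    }
  }
  structure(list(order = order, h = 1, weights = w), class = "gl_weights")
}

#' @export
print.gl_weights <- function(x, ...) {
  cat(sprintf("# Grunwald-Letnikov weights, order %g, %d terms\n",
              x$order, length(x$weights)))
  print(head(x$weights, 10))
  invisible(x)
}

# dense lower-triangular (in band index) operator: out[i] = sum_m w_m x[i-m],
# expanding window from the first band. Returned as the n x n matrix T with
# X_out = X %*% T, shared by the vector and matrix paths so they agree exactly.
gl_operator <- function(order, n) {
  w <- gl_weights(order, n)$weights
  op <- matrix(0, n, n)
  for (m in 0:(n - 1)) {
    if (w[m + 1] == 0) next
    j <- (m + 1):n
    op[cbind(j - m, j)] <- w[m + 1]
  }
  op
}

#' Fractional derivative of a uniformly sampled signal
#'
#' Applies the discrete Grunwald-Letnikov operator with unit step and an
#' expanding window anchored at the first sample:
#' `out[i] = sum_{m=0}^{i-1} w_m x[i-m]`. Output length equals input length;
#' the operator is linear in `x`, reduces to the identity at order 0 and to
#' the classical difference stencils at integer orders.
#'
#' @param x Finite numeric vector sampled on a uniform grid.
#' @param order Differentiation order `v >= 0`.
#' @return Numeric vector, same length as `x`.
#' @export
fractional_derivative <- function(x, order) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x))) {
    abort_fracspec("signal must be finite numeric.", "fracspec_error_validation")
  }
  n <- length(x)
  as.vector(matrix(x, 1) %*% gl_operator(order, n))
}

#' Fractionally differentiate every spectrum of a table
#'
#' Row-wise [fractional_derivative()] on the reflectance matrix. Only raw
#' (order 0) tables are accepted, so a differentiated table cannot be
#' differentiated a second time by accident.
#'
#' @param s A [spectra_set()] at order 0.
#' @param order Differentiation order `v >= 0`.
#' @param trim Number of leading bands to drop from the result (those early
#'   bands have a short differencing history); default 0 keeps the full
#'   400-2500 nm axis.
#' @return A [spectra_set()] whose order attribute equals `order`.
#' @export
transform_set <- function(s, order, trim = 0) {
  check_spectra_set(s)
  if (spectra_order(s) != 0) {
    abort_fracspec(
      sprintf("spectra are already differentiated (order %g); transform_set() requires order-0 input.",
              spectra_order(s)),
      "fracspec_error_state"
    )
  }
  x <- spectra_matrix(s)
  wl <- spectra_wavelengths(s)
  out <- x %*% gl_operator(order, ncol(x))
  if (trim > 0) {
    keep <- (trim + 1):ncol(out)
    out <- out[, keep, drop = FALSE]
    wl <- wl[keep]
  }
  res <- spectra_set(s$sample_id, s$potassium, out, wl, order = order)
  attr(res, "trimmed_bands") <- trim
  res
}

#' Differentiate a spectra table over a sweep of orders
#'
#' @param s A [spectra_set()] at order 0.
#' @param orders Numeric vector of orders, each `>= 0`; default is the
#'   0 to 3 sweep at 0.1 intervals (31 orders).
#' @param trim Passed to [transform_set()].
#' @return Named list (names `"0.0"`, `"0.1"`, ...) of differentiated
#'   [spectra_set()]s, one per order.
#' @export
sweep_orders <- function(s, orders = seq(0, 3, by = 0.1), trim = 0) {
  if (length(orders) == 0) {
    abort_fracspec("orders must be non-empty.", "fracspec_error_domain")
  }
  if (any(orders < 0)) {
    abort_fracspec("orders must all be >= 0.", "fracspec_error_domain")
  }
  out <- map(orders, function(v) transform_set(s, v, trim = trim))
  names(out) <- format_order(orders)
  out
}

format_order <- function(v) sprintf("%.1f", v)
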