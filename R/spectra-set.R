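#' Spectra tables
#'
#' A `spectra_set` is a tibble with one row per sample: a `sample_id` column,
#' a `potassium` column (leaf potassium content in units of 10 g/kg), and one
#' numeric reflectance column per wavelength on a uniform 1-nm grid. The
#' differentiation order of the stored matrix is carried as an attribute
#' (`0` for raw reflectance); all downstream operators check it so that, for
#' example, an already-differentiated table cannot be differentiated twice by
#' accident.
#'
#' Invariants enforced at construction:
#' * reflectance has one column per wavelength and one row per sample;
#' * wavelengths are strictly increasing with exact 1-nm spacing;
#' * all reflectance values are finite, and lie in \[0, 1\] at order 0;
#' * potassium values are finite and strictly positive.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param potassium Numeric vector of potassium contents (10 g/kg), one per
#'   sample, strictly positive.
#' @param reflectance Numeric matrix, samples x bands.
#' @param wavelengths Numeric vector of band centres in nm.
#' @param order Differentiation order of the stored matrix (default 0).
#' @return A `spectra_set` tibble.
#' @export
spectra_set <- function(sample_id, potassium, reflectance, wavelengths,
                        order = 0) {
  reflectance <- as.matrix(reflectance)
  sample_id <- as.character(sample_id)
  validate_spectra_inputs(sample_id, potassium, reflectance, wavelengths, order)
  colnames(reflectance) <- format_wavelength(wavelengths)
  out <- new_tibble(
    c(list(sample_id = sample_id, potassium = as.numeric(potassium)),
      as.list(as.data.frame(reflectance, optional = TRUE))),
    nrow = length(sample_id),
    class = "spectra_set"
  )
  attr(out, "wavelengths") <- as.numeric(wavelengths)
  attr(out, "order") <- as.numeric(order)
  out
}

format_wavelength <- function(wl) format(wl, trim = TRUE, scientific = FALSE)

validate_spectra_inputs <- function(sample_id, potassium, reflectance,
                                    wavelengths, order) {
  n <- length(sample_id)
  if (nrow(reflectance) != n || length(potassium) != n) {
    abort_fracspec(
      sprintf(
        "sample_id (%d), potassium (%d) and reflectance rows (%d) must agree.",
        n, length(potassium), nrow(reflectance)
      ),
      "fracspec_error_validation"
    )
  }
  if (ncol(reflectance) != length(wavelengths)) {
    abort_fracspec(
      sprintf(
        "reflectance has %d columns but %d wavelengths were given.",
        ncol(reflectance), length(wavelengths)
      ),
      "fracspec_error_validation"
    )
  }
  if (length(wavelengths) >= 2) {
    d <- diff(wavelengths)
    if (any(d <= 0)) {
      abort_fracspec("wavelengths must be strictly increasing.",
                     "fracspec_error_validation")
    }
    if (any(abs(d - 1) > 1e-8)) {
      abort_fracspec(
        "wavelength spacing must be exactly 1 nm; resample first (see resample_to_grid()).",
        "fracspec_error_validation"
      )
    }
  }
  if (anyNA(reflectance) || !all(is.finite(reflectance))) {
    bad <- sample_id[apply(reflectance, 1, function(r) any(!is.finite(r)))]
    abort_fracspec(
      paste0("reflectance contains missing or non-finite values in sample(s): ",
             paste(bad, collapse = ", ")),
      "fracspec_error_validation"
    )
  }
  if (anyNA(potassium) || any(!is.finite(potassium)) || any(potassium <= 0)) {
    bad <- sample_id[!is.finite(potassium) | potassium <= 0]
    abort_fracspec(
      paste0("potassium must be finite and strictly positive; offending sample(s): ",
             paste(bad, collapse = ", ")),
      "fracspec_error_validation"
    )
  }
  if (order == 0 && (min(reflectance) < 0 || max(reflectance) > 1)) {
    abort_fracspec(
      "raw (order 0) reflectance must lie in [0, 1].",
      "fracspec_error_validation"
    )
  }
  invisible(TRUE)
}

#' Accessors for spectra tables
#'
#' @param s A [spectra_set()].
#' @return `spectra_matrix()` the samples x bands reflectance matrix;
#'   `spectra_wavelengths()` the wavelength grid in nm; `spectra_order()` the
#'   differentiation order of the stored matrix.
#' @export
spectra_matrix <- function(s) {
  check_spectra_set(s)
  wl <- attr(s, "wavelengths")
  m <- as.matrix(s[, format_wavelength(wl), drop = FALSE])
  rownames(m) <- s$sample_id
  m
}

#' @rdname spectra_matrix
#' @export
spectra_wavelengths <- function(s) {
  check_spectra_set(s)
  attr(s, "wavelengths")
}

#' @rdname spectra_matrix
#' @export
spectra_order <- function(s) {
  check_spectra_set(s)
  attr(s, "order")
}

check_spectra_set <- function(s) {
  if (!inherits(s, "spectra_set")) {
    abort_fracspec("expected a spectra_set.", "fracspec_error_validation")
  }
  invisible(TRUE)
}

#' Subset samples of a spectra table
#'
#' Row subsetting that preserves the wavelength grid and order attributes;
#' used e.g. to carve the train/validation split out of a full table.
#'
#' @param s A [spectra_set()].
#' @param idx Integer vector of row indices.
#' @return A `spectra_set` with the selected samples.
#' @export
slice_samples <- function(s, idx) {
  check_spectra_set(s)
  spectra_set(
    sample_id = s$sample_id[idx],
    potassium = s$potassium[idx],
    reflectance = spectra_matrix(s)[idx, , drop = FALSE],
    wavelengths = spectra_wavelengths(s),
    order = spectra_order(s)
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  wl <- attr(x, "wavelengths")
  cat(sprintf(
    "# spectra_set: %d samples x %d bands (%g-%g nm), differentiation order %g\n",
    nrow(x), length(wl), min(wl), max(wl), attr(x, "order")
  ))
  NextMethod()
}
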