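#' Read a wide-format spectra table
#'
#' Reads a CSV with one row per sample: an id column, a potassium column
#' (units of 10 g/kg) and one reflectance column per wavelength. Wavelength
#' columns are recognised by name: either bare numbers (`"400"`) or numbers
#' with a non-numeric prefix (`"X400"`, `"wl_400"`). Columns are sorted into
#' ascending wavelength order, so shuffled input columns yield the same table.
#'
#' @param path Path to the CSV file.
#' @param id_col,potassium_col Names of the identifier and potassium columns.
#' @param resample If `TRUE` (default), input not on a 1-nm grid is linearly
#'   resampled onto one spanning its own range; if `FALSE`, such input is an
#'   error.
#' @return A [spectra_set()] at differentiation order 0.
#' @export
read_spectra_table <- function(path, id_col = "sample_id",
                               potassium_col = "potassium",
                               resample = TRUE) {
  if (!file.exists(path)) {
    abort_fracspec(paste0("file not found: ", path), "fracspec_error_io")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c(id_col, potassium_col)) {
    if (!col %in% names(raw)) {
      abort_fracspec(
        sprintf("malformed header: required column '%s' is missing.", col),
        "fracspec_error_format"
      )
    }
  }
  band_names <- setdiff(names(raw), c(id_col, potassium_col))
  wl <- parse_wavelength_names(band_names)
  if (length(wl) < 2) {
    abort_fracspec(
      "need at least 2 numeric wavelength columns.",
      "fracspec_error_format"
    )
  }
  ord <- order(wl)
  wl <- wl[ord]
  band_names <- band_names[ord]
  refl <- as.matrix(raw[, band_names])
  if (!is.numeric(refl)) {
    bad <- band_names[!vapply(raw[, band_names], is.numeric, logical(1))]
    abort_fracspec(
      paste0("non-numeric reflectance column(s): ", paste(bad, collapse = ", ")),
      "fracspec_error_format"
    )
  }
  ids <- as.character(raw[[id_col]])
  if (anyNA(refl)) {
    bad <- ids[apply(refl, 1, anyNA)]
    abort_fracspec(
      paste0("missing reflectance value(s) in sample(s): ",
             paste(bad, collapse = ", ")),
      "fracspec_error_validation"
    )
  }
  k <- raw[[potassium_col]]
  if (anyNA(k) || any(k <= 0)) {
    bad <- ids[is.na(k) | k <= 0]
    abort_fracspec(
      paste0("potassium must be positive; offending sample(s): ",
             paste(bad, collapse = ", ")),
      "fracspec_error_validation"
    )
  }
  uniform <- length(wl) >= 2 && all(abs(diff(wl) - 1) < 1e-8)
  if (!uniform) {
    if (!resample) {
      abort_fracspec(
        "input wavelengths are not on a uniform 1-nm grid and resample = FALSE.",
        "fracspec_error_format"
      )
    }
    s <- spectra_set_nonuniform(ids, k, refl, wl)
    return(resample_to_grid(s, ceiling(min(wl)), floor(max(wl))))
  }
  spectra_set(ids, k, refl, wl, order = 0)
}

# strip any non-numeric prefix (dialects "400", "X400", "wl_400")
parse_wavelength_names <- function(nms) {
  x <- sub("^[^0-9]*", "", nms)
  wl <- suppressWarnings(as.numeric(x))
  if (anyNA(wl)) {
    abort_fracspec(
      paste0("column name(s) not parseable as wavelengths: ",
             paste(nms[is.na(wl)], collapse = ", ")),
      "fracspec_error_format"
    )
  }
  wl
}

# internal pre-resampling holder: skips the 1-nm spacing invariant
spectra_set_nonuniform <- function(ids, k, refl, wl) {
  out <- list(sample_id = ids, potassium = as.numeric(k),
              reflectance = refl, wavelengths = wl)
  class(out) <- "spectra_raw_grid"
  out
}

#' Resample spectra onto a uniform 1-nm wavelength grid
#'
#' Linear interpolation of each sample's spectrum onto the integer-nm grid
#' `start_nm:end_nm`. Values at wavelengths shared between the input and the
#' target grid are preserved exactly, so resampling data already on the target
#' grid is the identity.
#'
#' @param s A [spectra_set()] (or the internal pre-validation grid holder).
#' @param start_nm,end_nm Target grid limits in nm; must lie within the data's
#'   wavelength range.
#' @return A [spectra_set()] on the 1-nm grid `start_nm:end_nm`.
#' @export
resample_to_grid <- function(s, start_nm = 400, end_nm = 2500) {
  if (inherits(s, "spectra_set")) {
    wl <- spectra_wavelengths(s)
    refl <- spectra_matrix(s)
    ids <- s$sample_id
    k <- s$potassium
    ord <- spectra_order(s)
  } else if (inherits(s, "spectra_raw_grid")) {
    wl <- s$wavelengths
    refl <- s$reflectance
    ids <- s$sample_id
    k <- s$potassium
    ord <- 0
  } else {
    abort_fracspec("expected a spectra_set.", "fracspec_error_validation")
  }
  if (start_nm < min(wl) || end_nm > max(wl) || start_nm >= end_nm) {
    abort_fracspec(
      sprintf("requested grid [%g, %g] nm exceeds data range [%g, %g] nm.",
              start_nm, end_nm, min(wl), max(wl)),
      "fracspec_error_range"
    )
  }
  grid <- seq(start_nm, end_nm, by = 1)
  if (length(wl) == length(grid) && all(wl == grid)) {
    if (inherits(s, "spectra_set")) return(s)
    return(spectra_set(ids, k, refl, wl, order = ord))
  }
  out <- matrix(NA_real_, nrow(refl), length(grid))
  for (i in seq_len(nrow(refl))) {
    out[i, ] <- approx(wl, refl[i, ], xout = grid, method = "linear")$y
  }
  # exact pass-through at shared grid points (approx() is exact there, but be
  # explicit so the invariant does not depend on interpolation arithmetic)
  shared <- intersect(wl, grid)
  if (length(shared)) {
    out[, match(shared, grid)] <- refl[, match(shared, wl)]
  }
  spectra_set(ids, k, out, grid, order = ord)
}

#' Write a spectra table to CSV
#'
#' Inverse of [read_spectra_table()]: header `sample_id,potassium,400,...`.
#'
#' @param s A [spectra_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(s, path) {
  check_spectra_set(s)
  readr::write_csv(as_tibble(s), path, progress = FALSE)
  invisible(path)
}

#' Write or read a model-comparison table
#'
#' Tidy CSV with one row per (model, order, split) and columns
#' `model, order, split, r2, mse, mae, n_components, hyperparams, seed, error`.
#' Floats are written at full (round-trip) precision so
#' `read_comparison_table(write_comparison_table(t))` is the identity.
#'
#' @param t A comparison table from [run_experiment()].
#' @param path File path.
#' @return `write_comparison_table()` returns `path` invisibly;
#'   `read_comparison_table()` returns the table.
#' @export
write_comparison_table <- function(t, path) {
  if (!is.data.frame(t) || nrow(t) == 0) {
    abort_fracspec("comparison table must be a non-empty data frame.",
                   "fracspec_error_validation")
  }
  readr::write_csv(as_tibble(t), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_comparison_table
#' @export
read_comparison_table <- function(path) {
  if (!file.exists(path)) {
    abort_fracspec(paste0("file not found: ", path), "fracspec_error_io")
  }
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      model = readr::col_character(),
      order = readr::col_double(),
      split = readr::col_character(),
      r2 = readr::col_double(),
      mse = readr::col_double(),
      mae = readr::col_double(),
      n_components = readr::col_integer(),
      hyperparams = readr::col_character(),
      seed = readr::col_integer(),
      error = readr::col_character()
    ),
    progress = FALSE
  )
  class(out) <- c("comparison_tbl", class(out))
  out
}
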