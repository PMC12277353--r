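# Small deterministic fixtures built in code.

# tiny spectra table on an arbitrary 1-nm grid
toy_spectra <- function(n = 3, bands = 5, start_nm = 400, seed = 1,
                        potassium = NULL) {
  set.seed(seed)
  refl <- matrix(runif(n * bands, 0.1, 0.9), n, bands)
  spectra_set(
    sample_id = sprintf("T%02d", seq_len(n)),
    potassium = potassium %||% runif(n, 0.2, 2),
    reflectance = refl,
    wavelengths = seq(start_nm, length.out = bands),
    order = 0
  )
}

write_toy_csv <- function(s, path = withr::local_tempfile(fileext = ".csv",
                                                          .local_envir = parent.frame())) {
  write_spectra_table(s, path)
  path
}

`%||%` <- rlang::`%||%`

# direct Gamma-ratio evaluation of the generalised binomial weights; the
# independent oracle for the recursion (valid away from Gamma poles)
gamma_ratio_weights <- function(v, length) {
  m <- 0:(length - 1)
  (-1)^m * gamma(v + 1) / (factorial(m) * gamma(v - m + 1))
}

# naive expanding-window evaluation of the fractional derivative
naive_fractional_derivative <- function(x, v) {
  w <- gl_weights(v, length(x))$weights
  vapply(seq_along(x), function(i) sum(w[1:i] * x[i:1]), numeric(1))
}
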