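test_that("a wide CSV round-trips into a validated spectra table", {
  s <- toy_spectra(n = 3, bands = 5)
  path <- write_toy_csv(s)
  got <- read_spectra_table(path)
  expect_s3_class(got, "spectra_set")
  expect_equal(dim(spectra_matrix(got)), c(3, 5))
  expect_equal(spectra_wavelengths(got), 400:404)
  expect_equal(spectra_order(got), 0)
  expect_equal(spectra_matrix(got), spectra_matrix(s))
  expect_equal(got$potassium, s$potassium)

  # read -> write -> read is the identity
  path2 <- write_toy_csv(got)
  expect_equal(read_spectra_table(path2), got)
})

test_that("column order and naming dialects do not change the result", {
  s <- toy_spectra(n = 3, bands = 5)
  path <- write_toy_csv(s)
  df <- readr::read_csv(path, show_col_types = FALSE)
  shuffled <- df[, c("403", "sample_id", "400", "404", "potassium", "402", "401")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, p2)
  expect_equal(read_spectra_table(p2), read_spectra_table(path))

  prefixed <- df
  names(prefixed) <- sub("^(\\d+)$", "X\\1", names(prefixed))
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(prefixed, p3)
  expect_equal(read_spectra_table(p3), read_spectra_table(path))
})

test_that("validation failures name the offending rows and columns", {
  s <- toy_spectra(n = 3, bands = 5)
  df <- readr::read_csv(write_toy_csv(s), show_col_types = FALSE)

  holey <- df
  holey[2, "402"] <- NA
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(holey, p)
  expect_error(read_spectra_table(p), "T02", class = "fracspec_error_validation")

  nok <- df
  nok$potassium[c(1, 3)] <- c(-1, 0)
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(nok, p2)
  err <- expect_error(read_spectra_table(p2),
                      class = "fracspec_error_validation")
  expect_match(conditionMessage(err), "T01")
  expect_match(conditionMessage(err), "T03")

  nop <- df[, setdiff(names(df), "potassium")]
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(nop, p3)
  expect_error(read_spectra_table(p3), "potassium",
               class = "fracspec_error_format")
})

test_that("resampling is the identity on the target grid and linear otherwise", {
  s <- toy_spectra(n = 2, bands = 11)
  expect_identical(resample_to_grid(s, 400, 410), s)

  # two bands at 400 and 402 nm -> linear midpoint at 401 nm
  df <- tibble::tibble(sample_id = "A", potassium = 1,
                       `400` = 0.2, `402` = 0.4)
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, p)
  got <- read_spectra_table(p)
  expect_equal(spectra_wavelengths(got), 400:402)
  expect_equal(as.numeric(spectra_matrix(got)), c(0.2, 0.3, 0.4))

  # shared grid points pass through exactly
  s2 <- toy_spectra(n = 2, bands = 11)
  sub <- resample_to_grid(s2, 402, 408)
  expect_identical(spectra_matrix(sub), spectra_matrix(s2)[, 3:9])

  expect_error(resample_to_grid(s, 399, 410), class = "fracspec_error_range")
})

test_that("the working range restriction keeps 2101 of a 350-2500 nm grid", {
  set.seed(4)
  n_band <- length(350:2500)
  s_raw <- tibble::tibble(
    sample_id = c("A", "B"), potassium = c(0.5, 1.5),
    !!!stats::setNames(as.list(as.data.frame(matrix(runif(2 * n_band, 0.2, 0.8),
                                                    2, n_band))),
                       as.character(350:2500))
  )
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(s_raw, p)
  s <- read_spectra_table(p)
  trimmed <- resample_to_grid(s, 400, 2500)
  expect_equal(length(spectra_wavelengths(trimmed)), 2101)
  expect_equal(range(spectra_wavelengths(trimmed)), c(400, 2500))
})

test_that("comparison tables round-trip losslessly through CSV", {
  one <- tibble::tibble(
    model = "plsr", order = 0.8, split = c("train", "validation"),
    r2 = c(0.76123456789, 0.5101112), mse = c(0.21, 0.94), mae = c(0.33, 0.62),
    n_components = c(7L, 7L), hyperparams = "n_components=7",
    seed = 11L, error = NA_character_
  )
  p <- withr::local_tempfile(fileext = ".csv")
  write_comparison_table(one, p)
  lines <- readLines(p)
  expect_length(lines, 3) # header + train + validation
  got <- read_comparison_table(p)
  expect_equal(tibble::as_tibble(got), one)

  # a full seven-model, 31-order sweep writes 7 x 31 x 2 data rows
  grid <- expand.grid(
    model = c("plsr", "rf", "xgb", "mlp", "plsr-rf", "plsr-xgb", "plsr-mlp"),
    order = seq(0, 3, by = 0.1), split = c("train", "validation"),
    stringsAsFactors = FALSE
  )
  big <- tibble::as_tibble(grid) |>
    dplyr::mutate(r2 = 0.5, mse = 1, mae = 0.7, n_components = 5L,
                  hyperparams = "x=1", seed = 1L, error = NA_character_)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_comparison_table(big, p2)
  expect_length(readLines(p2), 7 * 31 * 2 + 1)

  expect_error(write_comparison_table(big[0, ], p2),
               class = "fracspec_error_validation")
})

test_that("construction invariants reject malformed tables", {
  expect_error(
    spectra_set("A", 1, matrix(0.5, 1, 3), c(400, 402, 403)),
    class = "fracspec_error_validation"
  ) # non-uniform grid
  expect_error(
    spectra_set(c("A", "B"), c(1, 2), matrix(1.5, 2, 2), 400:401),
    class = "fracspec_error_validation"
  ) # order-0 reflectance outside [0, 1]
  expect_error(
    spectra_set("A", 1, matrix(0.5, 1, 3), 400:402, order = 0) |>
      (\(s) spectra_set(s$sample_id, -1, spectra_matrix(s), 400:402))(),
    class = "fracspec_error_validation"
  ) # non-positive potassium
})
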