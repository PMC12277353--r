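test_that("the train/validation split has documented sizes and determinism", {
  s <- split_train_validation(10, 0.2, seed = 1)
  expect_length(s$train, 8)
  expect_length(s$validation, 2)

  s301 <- split_train_validation(301, 0.2, seed = 1)
  expect_length(s301$train, 240)
  expect_length(s301$validation, 61) # ceiling(301 * 0.2)
  expect_setequal(c(s301$train, s301$validation), 1:301)
  expect_length(intersect(s301$train, s301$validation), 0)

  expect_identical(split_train_validation(301, 0.2, seed = 7),
                   split_train_validation(301, 0.2, seed = 7))
  expect_error(split_train_validation(4, 0.2, 1),
               class = "fracspec_error_validation")
  expect_error(split_train_validation(10, 0, 1),
               class = "fracspec_error_domain")
})

test_that("regression metrics match hand-computed values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(r2 = 1, mse = 0, mae = 0))

  y <- c(1, 2, 3)
  m2 <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(m2$r2, 0)
  expect_equal(m2$mse, 2 / 3)
  expect_equal(m2$mae, 2 / 3)

  expect_warning(m3 <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "undefined")
  expect_true(is.na(m3$r2))
  expect_equal(m3$mse, 2 / 3)

  expect_error(regression_metrics(1:3, 1:2),
               class = "fracspec_error_validation")
})

tiny_config <- function(models, orders, seed = 5) {
  experiment_config(
    orders = orders, models = models,
    plsr_max_components = 5, plsr_cap = 8, cv_folds = 4,
    specs = list(
      rf = regressor_spec("random_forest",
                          grid = list(num.trees = 50, max.depth = 5,
                                      mtry = "sqrt"),
                          cv_folds = 4, seed = seed),
      `plsr-rf` = regressor_spec("random_forest",
                                 grid = list(num.trees = 50, max.depth = 5,
                                             mtry = "sqrt"),
                                 cv_folds = 4, seed = seed)
    ),
    seed = seed
  )
}

test_that("a small experiment produces a complete, well-formed table", {
  d <- generate_dataset(synth_config(n_samples = 40, seed = 21))
  cfg <- tiny_config(c("plsr", "plsr-rf"), orders = c(0, 0.5))
  tab <- run_experiment(d, cfg)

  expect_s3_class(tab, "comparison_tbl")
  expect_equal(nrow(tab), 2 * 2 * 2) # models x orders x splits
  expect_true(all(tab$split %in% c("train", "validation")))
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$mse >= 0 & tab$mae >= 0, na.rm = TRUE))
  expect_true(all(tab$r2 <= 1, na.rm = TRUE))
  expect_equal(sum(tab$model == "plsr-rf" & tab$split == "validation"), 2)
  # each (model, order) pair has exactly a train and a validation row
  counts <- dplyr::count(tab, model, order)
  expect_true(all(counts$n == 2))

  expect_error(run_experiment(transform_set(d, 1), cfg),
               class = "fracspec_error_state")
})

test_that("best-order selection maximises validation R2 with ties to lower order", {
  base <- tibble::tibble(
    model = "m", split = "validation", mse = 1, mae = 1,
    n_components = 1L, hyperparams = "x", seed = 1L, error = NA_character_
  )
  tab <- dplyr::bind_rows(
    dplyr::mutate(base, order = 0, r2 = 0.1),
    dplyr::mutate(base, order = 1, r2 = 0.5),
    dplyr::mutate(base, order = 2, r2 = 0.5)
  )
  best <- select_best(tab)
  expect_equal(best$order, 1) # tie broken toward the lower order
  expect_equal(best$r2, 0.5)

  single <- dplyr::mutate(base, order = 0.8, r2 = 0.3)
  expect_equal(select_best(single)$order, 0.8)

  # error-marked cells are excluded; fully failed models are dropped
  tab2 <- dplyr::bind_rows(
    tab,
    dplyr::mutate(base, model = "broken", order = 0, r2 = NA_real_,
                  error = "boom")
  )
  expect_warning(best2 <- select_best(tab2), "broken")
  expect_equal(best2$model, "m")
})

test_that("latent extraction and tuning never touch validation rows", {
  d <- generate_dataset(synth_config(n_samples = 40, seed = 31))
  cfg <- tiny_config("plsr-rf", orders = 0.5, seed = 9)
  split <- split_train_validation(nrow(d), cfg$validation_fraction,
                                  seed = cfg$seed)

  # poison the validation rows of a copy
  poisoned_matrix <- spectra_matrix(d)
  poisoned_matrix[split$validation, ] <-
    matrix(runif(length(split$validation) * 2101, 0.4, 0.6),
           length(split$validation))
  poisoned_k <- d$potassium
  poisoned_k[split$validation] <- rev(poisoned_k[split$validation])
  poisoned <- spectra_set(d$sample_id, poisoned_k, poisoned_matrix,
                          spectra_wavelengths(d), order = 0)

  t_clean <- run_experiment(d, cfg)
  t_poison <- run_experiment(poisoned, cfg)

  train_clean <- dplyr::filter(t_clean, split == "train")
  train_poison <- dplyr::filter(t_poison, split == "train")
  expect_identical(train_clean$r2, train_poison$r2)
  expect_identical(train_clean$mse, train_poison$mse)
  expect_identical(train_clean$hyperparams, train_poison$hyperparams)
  expect_identical(train_clean$n_components, train_poison$n_components)
  # while the validation metrics do change
  expect_false(identical(
    dplyr::filter(t_clean, split == "validation")$r2,
    dplyr::filter(t_poison, split == "validation")$r2
  ))
})

test_that("an experiment regenerates byte-identically from the same seed", {
  d <- generate_dataset(synth_config(n_samples = 40, seed = 41))
  cfg <- tiny_config("plsr-rf", orders = c(0, 1), seed = 13)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_comparison_table(run_experiment(d, cfg), p1)
  write_comparison_table(run_experiment(d, cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
})
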