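test_that("band-wise Pearson correlations match hand and library oracles", {
  y <- c(2, 2, 4)
  X <- cbind(a = c(1, 2, 3), b = y, c = -2 * y + 5, d = c(1, 1, 1))
  bc <- bandwise_correlation(X, y)
  expect_equal(bc$r[1], sqrt(3) / 2, tolerance = 1e-12) # 0.866...
  expect_equal(bc$r[2], 1)
  expect_equal(bc$r[3], -1)
  expect_true(is.na(bc$r[4])) # zero-variance band flagged, not 0

  # two-pass implementation vs stats::cor on random instances
  set.seed(9)
  for (i in 1:20) {
    Xr <- matrix(rnorm(30 * 6), 30)
    yr <- rnorm(30)
    expect_equal(bandwise_correlation(Xr, yr)$r, as.vector(cor(Xr, yr)),
                 tolerance = 1e-12)
  }

  expect_error(bandwise_correlation(X, c(1, 1, 1)),
               class = "fracspec_error_degenerate")
  expect_error(bandwise_correlation(X[1:2, ], y[1:2]),
               class = "fracspec_error_validation")
})

test_that("the correlation surface aggregates a sweep consistently", {
  d <- generate_dataset(synth_config(n_samples = 40, seed = 2))
  sw <- sweep_orders(d, orders = c(0, 0.5, 1))
  cs <- correlation_surface(sw)

  expect_true(all(cs$surface$abs_r >= 0 & cs$surface$abs_r <= 1, na.rm = TRUE))
  raw <- bandwise_correlation(d)
  at0 <- dplyr::filter(cs$surface, order == 0)
  expect_equal(at0$abs_r, abs(raw$r))
  expect_equal(nrow(cs$per_order_max), 3)
  expect_equal(
    cs$per_order_max$max_abs_r,
    vapply(sw, function(s) max(abs(bandwise_correlation(s)$r), na.rm = TRUE),
           numeric(1)),
    ignore_attr = TRUE
  )

  misaligned <- sw
  misaligned[[2]] <- slice_samples(misaligned[[2]], c(2:40, 1))
  expect_error(correlation_surface(misaligned),
               class = "fracspec_error_alignment")
})

test_that("the first PLS direction is the centred cross-covariance", {
  set.seed(11)
  X <- matrix(rnorm(40 * 12), 40)
  y <- rnorm(40)
  f <- fit_plsr(X, y, 1)
  xy <- crossprod(sweep(X, 2, colMeans(X)), y - mean(y))
  cosine <- sum(f$x_weights[, 1] * xy) / sqrt(sum(xy^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-12)
})

test_that("at full rank PLS1 reproduces the least-squares fit", {
  set.seed(21)
  for (i in 1:20) {
    X <- matrix(rnorm(20 * 5), 20)
    y <- rnorm(20)
    f <- fit_plsr(X, y, 5)
    ols <- stats::lm.fit(cbind(1, X), y)$fitted.values
    expect_equal(predict(f, X), ols, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("a noiseless linear response is fitted exactly", {
  set.seed(31)
  X <- matrix(rnorm(50 * 6), 50)
  beta <- c(2, -1, 0.5, 0, 3, -2)
  y <- as.vector(X %*% beta) + 4
  f <- fit_plsr(X, y, 6)
  r2 <- 1 - sum((y - predict(f, X))^2) / sum((y - mean(y))^2)
  expect_equal(r2, 1, tolerance = 1e-10)
})

test_that("training scores are orthogonal and projection is consistent", {
  set.seed(41)
  X <- matrix(rnorm(60 * 30), 60)
  y <- rnorm(60)
  f <- fit_plsr(X, y, 10)
  gram <- crossprod(f$scores)
  expect_lt(max(abs(gram - diag(diag(gram)))), 1e-8)
  expect_true(all(diff(f$cum_x_variance) >= -1e-12))
  expect_lte(f$cum_x_variance[f$n_components], 1 + 1e-12)
  expect_equal(unname(plsr_scores(f, X)), unname(f$scores), tolerance = 1e-10)
})

test_that("NIPALS agrees with an independent PLS implementation", {
  set.seed(2)
  X <- matrix(rnorm(30 * 8), 30, dimnames = list(NULL, paste0("b", 1:8)))
  y <- matrix(rnorm(30), dimnames = list(NULL, "y"))
  f <- fit_plsr(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  expect_equal(predict(f, X), unname(predict(mo, X)$predict[, 1, 3]),
               tolerance = 1e-10)
})

test_that("rank limits and degenerate responses raise typed errors", {
  X <- matrix(rnorm(10 * 4), 10)
  expect_error(fit_plsr(X, rnorm(10), 5), class = "fracspec_error_rank")
  expect_error(fit_plsr(X, rep(1, 10), 1), class = "fracspec_error_degenerate")
  # rank-1 predictors stop early with a warning
  X1 <- outer(rnorm(15), c(1, 2, 3))
  y <- X1[, 1] + rnorm(15, sd = 1e-8)
  expect_warning(f <- fit_plsr(X1, y, 3), "extracted")
  expect_lt(f$n_components, 3)
})

test_that("cross-validated component selection prefers parsimony", {
  set.seed(51)
  u <- rnorm(80)
  X <- outer(u, rnorm(10)) + matrix(rnorm(80 * 10, sd = 1e-4), 80)
  y <- 2 * u + 1
  expect_equal(as.integer(select_components_cv(X, y, max_components = 5,
                                               folds = 5, seed = 3)), 1L)
  expect_equal(as.integer(select_components_cv(X, y, max_components = 1,
                                               folds = 5, seed = 3)), 1L)
  # deterministic given the seed
  s1 <- select_components_cv(X, y, max_components = 5, folds = 5, seed = 9)
  s2 <- select_components_cv(X, y, max_components = 5, folds = 5, seed = 9)
  expect_identical(s1, s2)
})

test_that("the cumulative-variance rule stops at the documented component", {
  set.seed(61)
  # one dominant predictor direction carrying ~90% of the variance
  u <- rnorm(100)
  X <- outer(u, c(5, 4, 3, 0, 0)) + matrix(rnorm(500, sd = 0.45), 100)
  y <- u + rnorm(100, sd = 0.1)
  ex <- extract_latents_by_variance(X, y, threshold = 0.75)
  expect_equal(ex$model$n_components, 1)
  expect_true(ex$threshold_reached)
  expect_gte(ex$model$cum_x_variance[1], 0.75)
  # explicit variance bookkeeping: component variances sum to the explained share
  full <- suppressWarnings(fit_plsr(X, y, 4))
  Xc <- sweep(X, 2, colMeans(X))
  expl <- sum((full$scores %*% t(full$x_loadings))^2) / sum(Xc^2)
  expect_equal(full$cum_x_variance[full$n_components], expl, tolerance = 1e-10)

  expect_equal(extract_latents_by_variance(X, y, threshold = 1e-9)$model$n_components, 1)
  expect_warning(
    ex2 <- extract_latents_by_variance(X + matrix(rnorm(500, sd = 3), 100), y,
                                       threshold = 0.999, cap = 2),
    "cap"
  )
  expect_false(ex2$threshold_reached)
  expect_equal(ex2$model$n_components, 2)
})
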