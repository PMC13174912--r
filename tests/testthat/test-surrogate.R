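rand_descriptors <- function(n, p, seed) {
  set.seed(seed)
  matrix(runif(n * p), n, p)
}

test_that("Laplacian kernel matches its definition", {
  X <- rand_descriptors(5, 8, seed = 1)
  K <- laplacian_kernel(X, X, gamma = 0.3)
  # element-by-element recomputation from the formula
  for (i in 1:5) {
    for (j in 1:5) {
      expect_equal(K[i, j], exp(-0.3 * sum(abs(X[i, ] - X[j, ]))),
                   tolerance = 1e-12)
    }
  }
  expect_equal(diag(K), rep(1, 5))
  expect_true(all(K > 0 & K <= 1))
  expect_equal(laplacian_kernel(X, X, gamma = 1e-12),
               matrix(1, 5, 5), tolerance = 1e-9)
  expect_error(laplacian_kernel(X, X, gamma = 0), "positive")
  expect_error(laplacian_kernel(X, X[, 1:3], gamma = 1), "lengths differ")
})

test_that("fit interpolates as alpha -> 0 and matches a dense-solve oracle", {
  one <- matrix(1:4, 1, 4)
  m <- fit_surrogate(one, -7.5, alpha = 1e-10, gamma = 0.1)
  expect_equal(predict(m, one), -7.5, tolerance = 1e-6)

  X <- rand_descriptors(20, 6, seed = 2)
  set.seed(3)
  y <- rnorm(20, -5, 2)
  m <- fit_surrogate(X, y, alpha = 0.5, gamma = 0.2)
  # independent dense inversion oracle
  K <- outer(1:20, 1:20, Vectorize(function(i, j)
    exp(-0.2 * sum(abs(X[i, ] - X[j, ])))))
  coef_oracle <- qr.solve(K + 0.5 * diag(20), y)
  Xq <- rand_descriptors(7, 6, seed = 4)
  Kq <- outer(1:7, 1:20, Vectorize(function(i, j)
    exp(-0.2 * sum(abs(Xq[i, ] - X[j, ])))))
  expect_equal(m$coef, coef_oracle, tolerance = 1e-8)
  expect_equal(predict(m, Xq), as.numeric(Kq %*% coef_oracle),
               tolerance = 1e-8)

  # constant labels are reproduced exactly in the alpha -> 0 limit
  mc <- fit_surrogate(X, rep(-3, 20), alpha = 1e-12, gamma = 0.2)
  expect_equal(predict(mc, X), rep(-3, 20), tolerance = 1e-6)
})

test_that("prediction refuses a mismatched image-config hash", {
  X <- rand_descriptors(5, 4, seed = 5)
  m <- fit_surrogate(X, rnorm(5), alpha = 0.1, gamma = 0.1,
                     config_hash = "abc")
  expect_error(predict(m, X, config_hash = "def"), "mismatch")
  expect_silent(predict(m, X, config_hash = "abc"))
})

test_that("regression metrics match their definitions and flag zero variance", {
  y <- c(-1, -2, -3, -4)
  expect_equal(regression_metrics(y, y), c(r2 = 1, rmse = 0, mae = 0))
  m <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(unname(m["r2"]), 0)
  set.seed(6)
  yt <- rnorm(20)
  yp <- rnorm(20)
  m <- regression_metrics(yt, yp)
  expect_equal(unname(m["r2"]), 1 - sum((yt - yp)^2) / sum((yt - mean(yt))^2))
  expect_equal(unname(m["rmse"]), sqrt(mean((yt - yp)^2)))
  expect_equal(unname(m["mae"]), mean(abs(yt - yp)))
  expect_gte(m["rmse"], m["mae"])
  expect_warning(mz <- regression_metrics(rep(1, 3), c(1, 2, 3)), "zero variance")
  expect_true(is.na(mz["r2"]))
})

test_that("3-fold partitions of 345 rows give 230-row train and 115-row test sets", {
  X <- rand_descriptors(345, 5, seed = 7)
  set.seed(8)
  y <- rnorm(345, -5, 2)
  cv <- cross_validate(X, y, alpha = 0.1, gamma = 0.5, k = 3, seed = 1)
  expect_equal(cv$folds$n_train, rep(230, 3))
  expect_equal(cv$folds$n_test, rep(115, 3))
  expect_true(all(cv$folds[["test.rmse"]] >= cv$folds[["test.mae"]]))
  expect_true(all(cv$folds[["train.r2"]] <= 1))

  # degenerate k = n case runs (single-row test folds have undefined R^2)
  small <- suppressWarnings(
    cross_validate(X[1:3, ], y[1:3], alpha = 0.1, gamma = 0.5,
                   k = 3, seed = 1))
  expect_equal(small$folds$n_test, rep(1, 3))
  expect_error(cross_validate(X, y, 0.1, 0.5, k = 1), "at least 2")
})

test_that("cross-validation recovers a clean linear signal", {
  X <- rand_descriptors(120, 5, seed = 9)
  y <- as.numeric(X %*% c(3, -2, 1, 0, 0.5))
  cv <- cross_validate(X, y, alpha = 1e-6, gamma = 0.5, k = 3, seed = 2)
  expect_gt(cv$mean["test.r2"], 0.9)
})

test_that("grid search applies the one-standard-error rule deterministically", {
  X <- rand_descriptors(60, 4, seed = 10)
  set.seed(11)
  y <- as.numeric(X %*% c(2, -1, 0.5, 0)) + rnorm(60, 0, 0.1)
  single <- grid_search_one_se(X, y, alpha_grid = 0.3, gamma_grid = 0.7,
                               k = 3, seed = 3)
  expect_equal(single$alpha, 0.3)
  expect_equal(single$gamma, 0.7)

  gs1 <- grid_search_one_se(X, y, c(0.01, 0.1, 1), c(0.05, 0.5), k = 3, seed = 3)
  gs2 <- grid_search_one_se(X, y, c(0.01, 0.1, 1), c(0.05, 0.5), k = 3, seed = 3)
  expect_identical(gs1[c("alpha", "gamma")], gs2[c("alpha", "gamma")])
  expect_identical(gs1$metrics$mean, gs2$metrics$mean)
  # one-SE pick is at least as regularized as the raw best
  expect_gte(gs1$alpha, gs1$best$alpha)
  # every eligible config is within one se of the best
  expect_true(all(gs1$table$mean_test_r2 <= gs1$best$mean_test_r2 + 1e-12))
  expect_error(grid_search_one_se(X, y, numeric(0), 1), "nonempty")
})

test_that("one-SE rule prefers a more regularized config within one se of best", {
  # constructed landscape: large alpha slightly below the best score but
  # within its fold spread
  X <- rand_descriptors(90, 3, seed = 12)
  set.seed(13)
  y <- as.numeric(X %*% c(1, 1, 1)) + rnorm(90, 0, 0.3)
  gs <- grid_search_one_se(X, y, alpha_grid = c(0.001, 0.01, 0.1, 1),
                           gamma_grid = c(0.2), k = 3, seed = 4)
  eligible <- gs$table[gs$table$mean_test_r2 >=
                         gs$best$mean_test_r2 - gs$se, ]
  expect_equal(gs$alpha, max(eligible$alpha))
})
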