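test_that("design construction validates rank, size and variable roles", {
  tab <- data.frame(unit_id = letters[1:10], y = rnorm(10), x1 = rnorm(10))
  tab$x2 <- 2 * tab$x1
  expect_error(design_matrix(tab, "y", c("x1", "x2")), "x2")
  expect_error(design_matrix(tab, "y", "y"), "outcome")
  expect_error(design_matrix(tab[1:4, ], "y", "x1"), "few")
  d <- design_matrix(tab, "y", "x1")
  expect_equal(colnames(d$X), c("(Intercept)", "x1"))
})

test_that("OLS reproduces exact fits and the closed-form normal equations", {
  x <- 1:10
  tab <- data.frame(unit_id = as.character(1:10), y = 3 + 2 * x, x = x)
  fit <- suppressWarnings(fit_ols(design_matrix(tab, "y", "x")))
  expect_equal(unname(fit$coefficients$estimate), c(3, 2), tolerance = 1e-10)
  expect_equal(fit$r2_measure$value, 1, tolerance = 1e-10)

  set.seed(50)
  X <- cbind(1, matrix(rnorm(150), 50, 3))
  beta <- c(0.5, -1, 2, 0.3)
  y <- as.numeric(X %*% beta) + rnorm(50)
  tab2 <- data.frame(unit_id = as.character(1:50), y = y,
                     a = X[, 2], b = X[, 3], c = X[, 4])
  fit2 <- fit_ols(design_matrix(tab2, "y", c("a", "b", "c")))
  closed_form <- solve(crossprod(X), crossprod(X, y))
  expect_equal(fit2$coefficients$estimate, as.numeric(closed_form),
               tolerance = 1e-10)
})

test_that("spatial profile likelihoods collapse to OLS at the null parameter", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  ev <- weights_eigenvalues(W)
  set.seed(60)
  x1 <- rnorm(100)
  y <- 1 + 2 * x1 + rnorm(100)
  tab <- data.frame(unit_id = f$ids, y = y, x1 = x1)
  d <- design_matrix(tab, "y", "x1")
  ll_ols <- fit_ols(d)$log_likelihood
  expect_equal(slm_profile_loglik(W, d, 0, ev), ll_ols, tolerance = 1e-9)
  expect_equal(sem_profile_loglik(W, d, 0, ev), ll_ols, tolerance = 1e-9)
})

test_that("single-dataset ML fits recover the generating spatial parameters", {
  f <- make_grid_frame(20, 20)
  W <- row_standardize(queen_adjacency(f))
  ev <- weights_eigenvalues(W)
  set.seed(70)
  x1 <- rnorm(400)
  X <- cbind(1, x1)
  tab <- data.frame(unit_id = f$ids, y = NA, x1 = x1)

  tab$y <- simulate_slm(W, X, c(1, 2), delta = 0.5, sigma = 1, seed = 71)
  slm <- fit_spatial_lag(W, design_matrix(tab, "y", "x1"), ev = ev)
  expect_lt(abs(slm$spatial_parameter$estimate - 0.5), 0.15)
  expect_true(is.finite(slm$spatial_parameter$se) &&
                slm$spatial_parameter$se > 0)
  expect_equal(slm$aic, 2 * slm$k - 2 * slm$log_likelihood, tolerance = 1e-9)

  tab$y <- simulate_sem(W, X, c(1, 2), lambda = 0.7, sigma = 1, seed = 72)
  sem <- fit_spatial_error(W, design_matrix(tab, "y", "x1"), ev = ev)
  expect_lt(abs(sem$spatial_parameter$estimate - 0.7), 0.15)
  expect_gte(sem$r2_measure$value, 0)
  expect_lte(sem$r2_measure$value, 1)
  expect_equal(sem$aic, 2 * sem$k - 2 * sem$log_likelihood, tolerance = 1e-9)

  expect_error(fit_spatial_lag(queen_adjacency(f),
                               design_matrix(tab, "y", "x1")),
               "row-standardized")
})

test_that("eigenvalue log-determinant agrees with the dense determinant", {
  W <- row_standardize(queen_adjacency(make_grid_frame(5, 5)))
  ev <- weights_eigenvalues(W)
  ld_dense <- as.numeric(determinant(diag(25) - 0.4 * as.matrix(W$W),
                                     logarithm = TRUE)$modulus)
  expect_equal(sum(log(1 - 0.4 * ev)), ld_dense, tolerance = 1e-10)
})

test_that("model comparison ranks by AIC and rejects incompatible fits", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  ev <- weights_eigenvalues(W)
  set.seed(80)
  x1 <- rnorm(100)
  y <- simulate_sem(W, cbind(1, x1), c(1, 2), lambda = 0.6, sigma = 1,
                    seed = 81)
  tab <- data.frame(unit_id = f$ids, y = y, x1 = x1)
  d <- design_matrix(tab, "y", "x1")
  fits <- list(fit_ols(d), fit_spatial_lag(W, d, ev = ev),
               fit_spatial_error(W, d, ev = ev))
  cmp <- compare_models(fits)
  expect_equal(cmp$aic, sort(cmp$aic))
  expect_equal(cmp$rank, 1:3)
  # spatial likelihoods can never fall below their own null point = OLS
  expect_gte(fits[[2]]$log_likelihood, fits[[1]]$log_likelihood - 1e-9)
  expect_gte(fits[[3]]$log_likelihood, fits[[1]]$log_likelihood - 1e-9)

  f2 <- make_grid_frame(5, 5)
  W2 <- row_standardize(queen_adjacency(f2))
  set.seed(82)
  tab2 <- data.frame(unit_id = f2$ids, y = rnorm(25), x1 = rnorm(25))
  fit_small <- fit_ols(design_matrix(tab2, "y", "x1"))
  expect_error(compare_models(list(fits[[1]], fit_small)), "mismatched n")
})
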