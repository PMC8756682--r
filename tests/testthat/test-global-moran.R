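test_that("checkerboard on the 2x2 lattice gives exact perfect dispersion", {
  f <- make_grid_frame(2, 2)
  Wb <- shared_border_adjacency(f)
  x <- c(1, 0, 0, 1)
  expect_equal(global_moran(Wb, x, permutations = 0)$statistic, -1,
               tolerance = 1e-14)
  expect_equal(global_moran(row_standardize(Wb), x, permutations = 0)$statistic,
               -1, tolerance = 1e-14)
  expect_error(global_moran(Wb, rep(5, 4), permutations = 0), "constant")
})

test_that("vectorized statistic equals the naive double-loop formula", {
  for (seed in 1:6) {
    lat <- random_lattice(seed)
    set.seed(100 + seed)
    x <- rnorm(lat$n)
    y <- rnorm(lat$n)
    for (W in list(lat$binary, lat$rowstd)) {
      Wm <- as.matrix(W$W)
      expect_equal(global_moran(W, x, permutations = 0)$statistic,
                   naive_global_moran(Wm, x), tolerance = 1e-12)
      expect_equal(global_moran_bivariate(W, x, y, permutations = 0)$statistic,
                   naive_global_moran_biv(Wm, x, y), tolerance = 1e-12)
    }
  }
})

test_that("Moran's I is invariant to affine rescaling of the variable", {
  lat <- random_lattice(21)
  set.seed(5)
  x <- rnorm(lat$n)
  i0 <- global_moran(lat$rowstd, x, permutations = 0)$statistic
  expect_equal(global_moran(lat$rowstd, 3.7 * x - 12, permutations = 0)$statistic,
               i0, tolerance = 1e-12)
  expect_equal(global_moran(lat$rowstd, -2 * x, permutations = 0)$statistic,
               i0, tolerance = 1e-12)
})

test_that("bivariate Moran with y = x reduces exactly to the univariate statistic", {
  for (seed in c(2, 9)) {
    lat <- random_lattice(seed)
    set.seed(seed)
    x <- runif(lat$n, 10, 90)
    for (W in list(lat$binary, lat$rowstd)) {
      expect_equal(global_moran_bivariate(W, x, x, permutations = 0)$statistic,
                   global_moran(W, x, permutations = 0)$statistic,
                   tolerance = 1e-13)
    }
  }
})

test_that("permutation inference is seeded, floored for clustered data, and guards small R", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  # left half high, right half low: near-maximal clustering
  col <- as.integer(sub("^r\\d+c", "", f$ids))
  x <- as.numeric(col <= 5)
  p1 <- moran_permutation_test(W, x, permutations = 999, seed = 7)
  expect_equal(p1$pseudo_p, 0.001)
  p2 <- moran_permutation_test(W, x, permutations = 999, seed = 7)
  expect_identical(p1$pseudo_p, p2$pseudo_p)
  expect_identical(p1$null_mean, p2$null_mean)
  expect_error(moran_permutation_test(W, x, permutations = 5), ">= 19")
})

test_that("the permutation null is centred near -1/(n-1)", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  set.seed(31)
  x <- rnorm(100)
  perm <- moran_permutation_test(W, x, permutations = 9999, seed = 13)
  mc_err <- 3 * perm$null_sd / sqrt(perm$permutations)
  expect_lt(abs(perm$null_mean - (-1 / 99)), mc_err + 1e-4)
})

test_that("uncorrelated variables give a bivariate statistic inside the permutation null", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  set.seed(8)
  x <- rnorm(100)
  y <- rnorm(100)
  perm <- moran_permutation_test(W, x, y, permutations = 999, seed = 4)
  expect_lt(abs(perm$observed - perm$null_mean), 3 * perm$null_sd)
})

test_that("the result object records expectation, sample size and inference settings", {
  lat <- random_lattice(14)
  set.seed(1)
  x <- rnorm(lat$n)
  g <- global_moran(lat$rowstd, x, variable = "v", permutations = 99, seed = 3)
  expect_equal(g$expected_value, -1 / (lat$n - 1))
  expect_equal(g$n_units, lat$n)
  expect_equal(g$permutations, 99)
  expect_gte(g$pseudo_p, 1 / 100)
  expect_lte(g$pseudo_p, 1)
  expect_lt(abs(g$statistic), 1.5)
})
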