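test_that("local statistics match the naive per-unit loop and sum to S0 times global I", {
  for (seed in 1:4) {
    lat <- random_lattice(seed)
    set.seed(300 + seed)
    x <- rnorm(lat$n)
    y <- rnorm(lat$n)
    for (W in list(lat$binary, lat$rowstd)) {
      Wm <- as.matrix(W$W)
      st <- local_moran(W, x, permutations = 0)
      expect_equal(st$local_i, naive_local_moran(Wm, x), tolerance = 1e-12)
      expect_equal(sum(st$local_i),
                   W$s0 * global_moran(W, x, permutations = 0)$statistic,
                   tolerance = 1e-10)
      stb <- local_moran_bivariate(W, x, y, permutations = 0)
      expect_equal(stb$local_i, naive_local_moran_biv(Wm, x, y),
                   tolerance = 1e-12)
      expect_equal(sum(stb$local_i),
                   W$s0 * global_moran_bivariate(W, x, y,
                                                 permutations = 0)$statistic,
                   tolerance = 1e-10)
    }
  }
})

test_that("a central spike yields a high-low core surrounded by low-high neighbors", {
  f <- make_grid_frame(3, 3)
  W <- row_standardize(shared_border_adjacency(f))
  x <- rep(0, 9)
  x[5] <- 1  # center of the row-major 3x3 grid
  st <- local_moran(W, x, permutations = 0)
  expect_gt(st$z_value[5], 0)
  expect_lt(st$lag_value[5], 0)
  expect_equal(st$quadrant[5], "HL")
  edge <- c(2, 4, 6, 8)  # rook neighbors of the center
  expect_true(all(st$z_value[edge] < 0))
  expect_true(all(st$lag_value[edge] > 0))
  expect_equal(st$quadrant[edge], rep("LH", 4))
})

test_that("islands carry zero local statistics and the island label", {
  f <- squares_frame(c("A", "B", "C", "D"),
                     rbind(c(0, 0), c(1, 0), c(0, 1), c(9, 9)))
  W <- row_standardize(queen_adjacency(f))
  st <- local_moran(W, c(3, 9, 4, 7), permutations = 99, seed = 1)
  isl <- which(st$unit_id == "D")
  expect_equal(st$local_i[isl], 0)
  expect_equal(st$cluster_label[isl], "island")
  expect_true(is.na(st$pseudo_p[isl]))
  expect_true(is.na(st$quadrant[isl]))
})

test_that("bivariate LISA with y = x reproduces the univariate quadrants unit by unit", {
  lat <- random_lattice(17)
  set.seed(6)
  x <- runif(lat$n, 0, 100)
  uni <- local_moran(lat$rowstd, x, permutations = 0)
  biv <- local_moran_bivariate(lat$rowstd, x, x, permutations = 0)
  expect_equal(biv$quadrant, uni$quadrant)
  expect_equal(biv$local_i, uni$local_i, tolerance = 1e-12)
})

test_that("conditional permutation is seeded, floored for strong clusters, and guards small R", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  col <- as.integer(sub("^r\\d+c", "", f$ids))
  x <- as.numeric(col <= 5) + 0.01 * seq_len(100)  # strong cluster, no ties
  p1 <- conditional_permutation(W, x, permutations = 999, seed = 5)
  p2 <- conditional_permutation(W, x, permutations = 999, seed = 5)
  expect_identical(p1, p2)
  # interior units of each block are more extreme than any permutation draw
  expect_equal(min(p1), 1 / 1000)
  expect_gt(sum(p1 == 1 / 1000), 10)
  expect_error(conditional_permutation(W, x, permutations = 10), ">= 19")
})

test_that("cluster labels follow the quadrant/significance definition with the documented tie rule", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  set.seed(23)
  x <- simulate_sar_field(W, 0.8, seed = 23)
  st <- local_moran(W, x, permutations = 199, seed = 2, alpha = 0.05)
  sig <- !is.na(st$pseudo_p) & st$pseudo_p <= 0.05
  map <- c(HH = "hotspot", LL = "coldspot",
           HL = "high_low_outlier", LH = "low_high_outlier")
  expect_equal(st$cluster_label[sig], unname(map[st$quadrant[sig]]))
  expect_true(all(st$cluster_label[!sig] == "not_significant"))
  expect_error(classify_clusters(st, alpha = 1.5), "alpha")

  # a value exactly at the mean is tie-broken to the low side
  path <- from_adjacency_pairs(c("A", "B", "C"),
                               rbind(c("A", "B"), c("B", "C")))
  stp <- local_moran(row_standardize(path), c(1, 2, 3), permutations = 0)
  expect_equal(stp$z_value[2], 0)
  expect_true(stp$quadrant[2] %in% c("LL", "LH"))
  expect_equal(stp$quadrant[2], ifelse(stp$lag_value[2] > 0, "LH", "LL"))
})

test_that("raising alpha never removes significant labels and labels are scale invariant", {
  f <- make_grid_frame(8, 8)
  W <- row_standardize(queen_adjacency(f))
  set.seed(9)
  x <- simulate_sar_field(W, 0.7, seed = 9)
  st <- local_moran(W, x, permutations = 499, seed = 11)
  n_sig <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    sum(classify_clusters(st, a)$cluster_label != "not_significant"),
    numeric(1))
  expect_true(all(diff(n_sig) >= 0))

  st2 <- local_moran(W, 4 * x + 10, permutations = 499, seed = 11)
  expect_equal(st2$cluster_label, st$cluster_label)
  expect_equal(st2$local_i, st$local_i, tolerance = 1e-10)
})

test_that("cluster counts partition the units", {
  f <- squares_frame(c("A", "B", "C", "D"),
                     rbind(c(0, 0), c(1, 0), c(0, 1), c(9, 9)))
  W <- row_standardize(queen_adjacency(f))
  st <- local_moran(W, c(3, 9, 4, 7), permutations = 99, seed = 1)
  cc <- cluster_counts(st)
  expect_equal(sum(cc), 4)
  expect_equal(unname(cc["island"]), 1L)

  lat <- random_lattice(4)
  set.seed(2)
  st2 <- local_moran(lat$rowstd, rnorm(lat$n), permutations = 99, seed = 3)
  expect_equal(sum(cluster_counts(st2)), lat$n)
})

test_that("conditional permutation keeps its nominal level under spatial randomness", {
  f <- make_grid_frame(10, 10)
  W <- row_standardize(queen_adjacency(f))
  set.seed(42)
  fractions <- vapply(1:100, function(d) {
    x <- rnorm(100)
    mean(conditional_permutation(W, x, permutations = 999, seed = 42 + d) <= 0.05)
  }, numeric(1))
  rate <- mean(fractions)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})
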