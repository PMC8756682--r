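# Independent naive-loop oracles for the spatial statistics, plus shared
# fixtures. The oracles evaluate the printed double-sum formulas directly on
# a dense weight matrix and never touch the package's vectorized paths.

naive_global_moran <- function(Wm, x) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Wm[i, j] * (x[i] - xb) * (x[j] - xb)
      s0 <- s0 + Wm[i, j]
    }
  }
  (n / s0) * num / sum((x - xb)^2)
}

pop_z <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

naive_global_moran_biv <- function(Wm, x, y) {
  n <- length(x)
  zx <- pop_z(x)
  zy <- pop_z(y)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + Wm[i, j] * zx[i] * zy[j]
      s0 <- s0 + Wm[i, j]
    }
  }
  (n / s0) * num / sum(zy^2)
}

naive_local_moran <- function(Wm, x) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + Wm[i, j] * (x[j] - xb)
    out[i] <- n * (x[i] - xb) / denom * acc
  }
  out
}

naive_local_moran_biv <- function(Wm, x, y) {
  zx <- pop_z(x)
  zy <- pop_z(y)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + Wm[i, j] * zy[j]
    out[i] <- zx[i] * acc
  }
  out
}

# random rectangular lattice with queen weights, both styles
random_lattice <- function(seed, max_dim = 7) {
  set.seed(seed)
  r <- sample(3:max_dim, 1)
  c <- sample(3:max_dim, 1)
  frame <- make_grid_frame(r, c)
  Wb <- queen_adjacency(frame)
  list(frame = frame, binary = Wb, rowstd = row_standardize(Wb),
       n = r * c, rows = r, cols = c)
}

# a frame of unit squares at given lower-left corners
squares_frame <- function(ids, corners) {
  geoms <- lapply(seq_len(nrow(corners)), function(k) {
    x0 <- corners[k, 1]; y0 <- corners[k, 2]
    list(cbind(c(x0, x0 + 1, x0 + 1, x0, x0),
               c(y0, y0, y0 + 1, y0 + 1, y0)))
  })
  spatial_frame(ids, geoms)
}

# memoized fixtures shared across test files (the study-scale scenario and
# the spatial-error replicate study are each computed once per test run)
.fixture_cache <- new.env(parent = emptyenv())

get_paper_scenario <- function() {
  if (is.null(.fixture_cache$paper)) {
    .fixture_cache$paper <- make_district_scenario("paper_shape", seed = 42)
  }
  .fixture_cache$paper
}

# 50 spatial-error replicates on a 20x20 queen lattice at lambda = 0.7,
# beta = (1, 2), sigma = 1: all three models fitted per replicate
get_sem_replicate_study <- function() {
  if (!is.null(.fixture_cache$sem_study)) return(.fixture_cache$sem_study)
  frame <- make_grid_frame(20, 20)
  W <- row_standardize(queen_adjacency(frame))
  ev <- weights_eigenvalues(W)
  reps <- lapply(1:50, function(r) {
    set.seed(2000 + r)
    x1 <- rnorm(400)
    X <- cbind(1, x1)
    y <- simulate_sem(W, X, c(1, 2), lambda = 0.7, sigma = 1,
                      seed = 3000 + r)
    tab <- data.frame(unit_id = frame$ids, y = y, x1 = x1)
    d <- design_matrix(tab, "y", "x1")
    fits <- list(ols = fit_ols(d),
                 slm = fit_spatial_lag(W, d, ev = ev),
                 sem = fit_spatial_error(W, d, ev = ev))
    list(fits = fits,
         lambda_hat = fits$sem$spatial_parameter$estimate,
         beta_hat = fits$sem$coefficients$estimate,
         best = compare_models(fits)$model[1])
  })
  .fixture_cache$sem_study <- reps
  reps
}
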