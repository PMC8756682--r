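test_that("queen and shared-border degrees match hand enumeration on small grids", {
  f2 <- make_grid_frame(2, 2)
  Wq <- queen_adjacency(f2)
  expect_equal(as.numeric(Matrix::rowSums(Wq$W)), rep(3, 4))
  Wb <- shared_border_adjacency(f2)
  expect_equal(as.numeric(Matrix::rowSums(Wb$W)), rep(2, 4))

  f3 <- make_grid_frame(3, 3)
  qdeg <- as.numeric(Matrix::rowSums(queen_adjacency(f3)$W))
  bdeg <- as.numeric(Matrix::rowSums(shared_border_adjacency(f3)$W))
  # row-major: corners at 1,3,7,9; edges at 2,4,6,8; center at 5
  expect_equal(qdeg[c(1, 3, 7, 9)], rep(3, 4))
  expect_equal(qdeg[c(2, 4, 6, 8)], rep(5, 4))
  expect_equal(qdeg[5], 8)
  expect_equal(bdeg[c(1, 3, 7, 9)], rep(2, 4))
  expect_equal(bdeg[c(2, 4, 6, 8)], rep(3, 4))
  expect_equal(bdeg[5], 4)
})

test_that("disconnected units become islands and block global Moran", {
  f <- squares_frame(c("A", "B", "C"),
                     rbind(c(0, 0), c(10, 0), c(20, 0)))
  W <- queen_adjacency(f)
  expect_setequal(W$islands, c("A", "B", "C"))
  expect_equal(W$s0, 0)
  expect_error(global_moran(W, c(1, 2, 3), permutations = 0), "island")
})

test_that("binary weights are symmetric with s0 twice the edge count, and queen contains shared-border", {
  for (seed in 1:5) {
    lat <- random_lattice(seed)
    Wq <- lat$binary
    expect_true(Matrix::isSymmetric(Wq$W))
    expect_true(all(Wq$W@x %in% c(0, 1)))
    nb_q <- neighbor_sets(Wq)
    nb_b <- neighbor_sets(shared_border_adjacency(lat$frame))
    expect_equal(Wq$s0, 2 * sum(lengths(nb_q)) / 2)
    for (id in names(nb_b)) {
      expect_true(all(nb_b[[id]] %in% nb_q[[id]]))
    }
  }
})

test_that("from_adjacency_pairs builds the symmetric closure and validates input", {
  W <- from_adjacency_pairs(c("A", "B", "C"), rbind(c("A", "B")))
  expect_equal(as.numeric(W$W["A" == W$ids, ]), c(0, 1, 0),
               ignore_attr = TRUE)
  expect_true(Matrix::isSymmetric(W$W))
  expect_equal(W$islands, "C")
  expect_error(from_adjacency_pairs(c("A", "B"), rbind(c("A", "A"))), "self")
  expect_error(from_adjacency_pairs(c("A", "B"), rbind(c("A", "Z"))), "unknown")

  # round trip through the extracted pair list reproduces queen weights
  lat <- random_lattice(11)
  nb <- neighbor_sets(lat$binary)
  pairs <- do.call(rbind, lapply(names(nb), function(id) {
    if (length(nb[[id]]) == 0) return(NULL)
    cbind(id, nb[[id]])
  }))
  W2 <- from_adjacency_pairs(lat$frame$ids, pairs)
  expect_equal(as.matrix(W2$W), as.matrix(lat$binary$W), ignore_attr = TRUE)
})

test_that("row standardization yields unit row sums, correct s0, and is idempotent", {
  f <- make_grid_frame(2, 2)
  Wr <- row_standardize(shared_border_adjacency(f))
  expect_equal(unique(Wr$W@x), 0.5)
  expect_equal(Wr$s0, 4)

  lat <- random_lattice(3, max_dim = 8)
  Ws <- lat$rowstd
  expect_equal(as.numeric(Matrix::rowSums(Ws$W)), rep(1, lat$n),
               tolerance = 1e-12)
  expect_equal(Ws$s0, lat$n - length(Ws$islands))
  Ws2 <- row_standardize(Ws)
  expect_equal(as.matrix(Ws2$W), as.matrix(Ws$W), tolerance = 1e-15)

  # island rows stay zero after standardization
  fi <- squares_frame(c("A", "B", "C"), rbind(c(0, 0), c(1, 0), c(9, 9)))
  Wi <- row_standardize(queen_adjacency(fi))
  expect_equal(Wi$islands, "C")
  expect_equal(as.numeric(Matrix::rowSums(Wi$W)), c(1, 1, 0))
})

test_that("spatial lag is the weighted neighbor sum", {
  f <- make_grid_frame(2, 2)
  Wr <- row_standardize(shared_border_adjacency(f))
  # checkerboard: r1c1, r2c2 = 1; each cell's two rook neighbors are opposite
  x <- c(1, 0, 0, 1)
  expect_equal(spatial_lag(Wr, x), c(0, 1, 1, 0))
  expect_equal(spatial_lag(Wr, rep(7, 4)), rep(7, 4))

  Wb <- shared_border_adjacency(f)
  ind <- c(0, 1, 0, 0)  # indicator of unit 2 reads out column 2 of W
  expect_equal(spatial_lag(Wb, ind), as.numeric(Wb$W[, 2]))
  expect_error(spatial_lag(Wb, 1:3), "length")
})

test_that("contiguity works when touching vertices are not shared by both polygons", {
  # B's left edge spans A's right edge but with different vertices; C touches
  # A only at the corner point (0, 1)-(1, 1) region: classic T-junction
  f <- spatial_frame(
    c("A", "B", "C"),
    list(
      list(cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))),
      list(cbind(c(1, 2, 2, 1, 1), c(-1, -1, 2, 2, -1))),  # taller strip
      list(cbind(c(0, 1, 1, 0, 0), c(1, 1, 2, 2, 1)))
    ))
  Wq <- neighbor_sets(queen_adjacency(f))
  Wb <- neighbor_sets(shared_border_adjacency(f))
  expect_equal(Wq$A, c("B", "C"))
  expect_equal(Wb$A, c("B", "C"))
  expect_equal(Wb$C, c("A", "B"))
})
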