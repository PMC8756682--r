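#' Spatial contiguity weight matrices
#'
#' A `spatial_weights` object holds the sparse weight matrix W over the units
#' of a [spatial_frame()], with zeroes on the diagonal. Binary weights are
#' symmetric 0/1 contiguity indicators; row-standardized weights divide each
#' non-island row by its row sum so the spatial lag becomes a neighbor
#' average. `s0` is the aggregate of all weights, the normalising constant of
#' Moran's I.
#'
#' @name spatial_weights
NULL

.new_weights <- function(W, ids, style) {
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  n <- length(ids)
  degree <- Matrix::rowSums(W != 0)
  islands <- ids[degree == 0]
  structure(list(
    n = n, ids = ids, W = W, style = style,
    s0 = sum(W), islands = islands
  ), class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("<spatial_weights> ", x$n, " units, style = ", x$style,
      ", s0 = ", format(x$s0), ", links = ", Matrix::nnzero(x$W),
      ", islands = ", length(x$islands), "\n", sep = "")
  invisible(x)
}

#' Neighbor sets of a weight matrix
#' @param weights a `spatial_weights` object.
#' @return named list mapping each unit id to the character vector of its
#'   neighbors' ids (empty for islands).
#' @export
neighbor_sets <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  Wt <- methods::as(weights$W, "TsparseMatrix")
  i <- Wt@i + 1L
  j <- Wt@j + 1L
  out <- split(weights$ids[j], factor(i, levels = seq_len(weights$n)))
  names(out) <- weights$ids
  lapply(out, function(v) sort(unname(v)))
}

# --- geometry helpers -------------------------------------------------------

# snap coordinates to a grid of pitch `tol` (tol = 0 leaves them untouched)
.snap <- function(m, tol) {
  if (tol > 0) round(m / tol) * tol else m
}

# segments of one unit: matrix with columns x1 y1 x2 y2, all rings pooled
.unit_segments <- function(rings) {
  do.call(rbind, lapply(rings, function(r) {
    n <- nrow(r)
    cbind(r[-n, 1], r[-n, 2], r[-1, 1], r[-1, 2])
  }))
}

# minimum distance from each point (px, py) to segment set; returns TRUE if
# any point lies within tol of any segment
.any_point_near_segments <- function(pts, segs, tol) {
  for (s in seq_len(nrow(segs))) {
    x1 <- segs[s, 1]; y1 <- segs[s, 2]; x2 <- segs[s, 3]; y2 <- segs[s, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (pts[, 1] - x1)^2 + (pts[, 2] - y1)^2
    } else {
      t <- ((pts[, 1] - x1) * dx + (pts[, 2] - y1) * dy) / len2
      t <- pmin(1, pmax(0, t))
      d2 <- (pts[, 1] - (x1 + t * dx))^2 + (pts[, 2] - (y1 + t * dy))^2
    }
    if (any(d2 <= tol * tol)) return(TRUE)
  }
  FALSE
}

# TRUE if any segment of a overlaps collinearly with any segment of b over a
# length greater than tol
.any_collinear_overlap <- function(sa, sb, tol) {
  for (s in seq_len(nrow(sa))) {
    x1 <- sa[s, 1]; y1 <- sa[s, 2]; x2 <- sa[s, 3]; y2 <- sa[s, 4]
    ux <- x2 - x1; uy <- y2 - y1
    len <- sqrt(ux * ux + uy * uy)
    if (len == 0) next
    ux <- ux / len; uy <- uy / len
    # perpendicular distance of b's endpoints to the infinite line through a
    d1 <- abs(-uy * (sb[, 1] - x1) + ux * (sb[, 2] - y1))
    d2 <- abs(-uy * (sb[, 3] - x1) + ux * (sb[, 4] - y1))
    on_line <- d1 <= tol & d2 <= tol
    if (!any(on_line)) next
    # projections onto a's axis, overlap with [0, len]
    t1 <- ux * (sb[on_line, 1] - x1) + uy * (sb[on_line, 2] - y1)
    t2 <- ux * (sb[on_line, 3] - x1) + uy * (sb[on_line, 4] - y1)
    lo <- pmin(t1, t2); hi <- pmax(t1, t2)
    ov <- pmin(hi, len) - pmax(lo, 0)
    if (any(ov > tol)) return(TRUE)
  }
  FALSE
}

# candidate pairs by bbox overlap (expanded by tol)
.bbox_candidate_pairs <- function(bb, tol) {
  n <- nrow(bb)
  out_i <- integer(0); out_j <- integer(0)
  ord <- order(bb[, 1])
  for (a in seq_len(n - 1)) {
    i <- ord[a]
    for (b in (a + 1):n) {
      j <- ord[b]
      if (bb[j, 1] > bb[i, 3] + tol) break
      if (bb[j, 2] <= bb[i, 4] + tol && bb[i, 2] <= bb[j, 4] + tol) {
        out_i <- c(out_i, min(i, j)); out_j <- c(out_j, max(i, j))
      }
    }
  }
  cbind(out_i, out_j)
}

.contiguity <- function(frame, snap_tolerance, rule) {
  stopifnot(inherits(frame, "spatial_frame"))
  n <- n_units(frame)
  .assert(n >= 2, "contiguity needs at least 2 units")
  .assert(is.numeric(snap_tolerance) && snap_tolerance >= 0,
          "snap_tolerance must be non-negative")
  tol <- max(snap_tolerance, 1e-12)

  geoms <- lapply(frame$geoms, function(rings)
    lapply(rings, .snap, tol = snap_tolerance))
  for (u in seq_len(n)) {
    if (.unit_area(geoms[[u]]) <= tol * tol) {
      warning("unit ", frame$ids[u], " has (near) zero area", call. = FALSE)
    }
  }
  segs <- lapply(geoms, .unit_segments)
  verts <- lapply(geoms, function(rings)
    unique(do.call(rbind, lapply(rings, function(r) r[-nrow(r), , drop = FALSE]))))
  bb <- t(vapply(geoms, function(rings) {
    xy <- do.call(rbind, rings)
    c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  }, numeric(4)))

  cand <- .bbox_candidate_pairs(bb, tol)
  ei <- integer(0); ej <- integer(0)
  if (nrow(cand) > 0) {
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      hit <- if (rule == "queen") {
        .any_point_near_segments(verts[[i]], segs[[j]], tol) ||
          .any_point_near_segments(verts[[j]], segs[[i]], tol)
      } else {
        .any_collinear_overlap(segs[[i]], segs[[j]], tol)
      }
      if (hit) { ei <- c(ei, i); ej <- c(ej, j) }
    }
  }
  W <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei),
                            x = rep(1, 2 * length(ei)),
                            dims = c(n, n))
  .new_weights(W, frame$ids, "binary")
}

#' Queen contiguity weights from polygon geometry
#'
#' Two units are queen neighbors when their boundary point sets share at
#' least one point -- a shared border segment or a single shared corner both
#' count. Vertices are snapped to a grid of pitch `snap_tolerance` before the
#' intersection tests, absorbing the sub-micron vertex mismatch that
#' real-world boundary files routinely carry.
#'
#' @param frame a [spatial_frame()] with at least two units.
#' @param snap_tolerance snap grid pitch in coordinate units (default 1e-7).
#' @return binary symmetric `spatial_weights`; units with no neighbors are
#'   recorded in `$islands`.
#' @export
queen_adjacency <- function(frame, snap_tolerance = 1e-7) {
  .contiguity(frame, snap_tolerance, "queen")
}

#' Shared-border (rook-like) contiguity weights
#'
#' The stronger contiguity condition: two units are neighbors only when their
#' boundaries share a segment of positive length, so corner-only contact is
#' excluded. Every shared-border neighbor pair is also a queen neighbor pair.
#'
#' @inheritParams queen_adjacency
#' @return binary symmetric `spatial_weights`.
#' @export
shared_border_adjacency <- function(frame, snap_tolerance = 1e-7) {
  .contiguity(frame, snap_tolerance, "border")
}

#' Binary weights from an explicit adjacency pair list
#'
#' Bypasses geometry: the symmetric closure of the given id pairs becomes the
#' 0/1 entries. Useful for tests and for weights imported from neighbor
#' lists.
#'
#' @param ids ordered character vector of unit ids.
#' @param pairs a two-column matrix/data.frame of id pairs, or a list of
#'   length-2 character vectors.
#' @return binary `spatial_weights` over `ids` in the given order.
#' @export
from_adjacency_pairs <- function(ids, pairs) {
  ids <- as.character(ids)
  .assert(!anyDuplicated(ids), "duplicate ids")
  n <- length(ids)
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, function(p) as.character(p)))
  }
  if (is.null(pairs) || length(pairs) == 0) {
    return(.new_weights(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                             x = numeric(0), dims = c(n, n)),
                        ids, "binary"))
  }
  pairs <- as.matrix(pairs)
  .assert(ncol(pairs) == 2, "pairs must have two columns")
  a <- match(as.character(pairs[, 1]), ids)
  b <- match(as.character(pairs[, 2]), ids)
  bad <- is.na(a) | is.na(b)
  .assert(!any(bad), "unknown ids in pairs: ",
          paste(unique(c(pairs[is.na(a), 1], pairs[is.na(b), 2])), collapse = ", "))
  .assert(!any(a == b), "self-pairs are not allowed: ",
          paste(unique(pairs[a == b, 1]), collapse = ", "))
  W <- Matrix::sparseMatrix(i = c(a, b), j = c(b, a), x = rep(1, 2 * length(a)),
                            dims = c(n, n), use.last.ij = TRUE)
  W@x[] <- 1
  .new_weights(W, ids, "binary")
}

#' Row-standardize a binary weight matrix
#'
#' Divides every non-island row by its row sum so each row sums to one and
#' the spatial lag becomes the neighbor mean; island rows stay all-zero. The
#' resulting `s0` equals the number of non-island units. Applying the
#' function to an already standardized matrix is the identity.
#'
#' @param weights a `spatial_weights` object.
#' @return `spatial_weights` with style `"row_standardized"`.
#' @export
row_standardize <- function(weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  rs <- Matrix::rowSums(weights$W)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  W <- Matrix::Diagonal(x = scale) %*% weights$W
  out <- .new_weights(W, weights$ids, "row_standardized")
  out
}

#' Spatial lag of a variable
#'
#' Computes `(Wx)_i = sum_j w_ij x_j`. For row-standardized weights this is
#' the mean of `x` over unit i's neighbors; islands get 0.
#'
#' @param weights a `spatial_weights` object.
#' @param x numeric vector in the weight matrix's unit order.
#' @return numeric vector of spatial lags.
#' @export
spatial_lag <- function(weights, x) {
  stopifnot(inherits(weights, "spatial_weights"))
  .check_numeric_vector(x, weights$n)
  as.numeric(weights$W %*% x)
}

# real eigenvalues of W, used for the admissible interval of spatial
# autoregressive parameters and for the log-determinant
.weights_eigenvalues <- function(weights) {
  ev <- eigen(as.matrix(weights$W), only.values = TRUE)$values
  if (is.complex(ev)) {
    if (max(abs(Im(ev))) > 1e-8) {
      warning("weight matrix has complex eigenvalues; using real parts",
              call. = FALSE)
    }
    ev <- Re(ev)
  }
  ev
}

#' Eigenvalues of a weight matrix
#'
#' One-time dense eigenvalue decomposition of W, used to delimit the
#' admissible interval of the spatial autoregressive parameter and to
#' evaluate the log-determinant term of the spatial likelihoods. Computing it
#' once and passing it to repeated fits on the same W avoids redundant work.
#'
#' @param weights a `spatial_weights` object.
#' @return numeric vector of (real) eigenvalues.
#' @export
weights_eigenvalues <- function(weights) .weights_eigenvalues(weights)

# admissible open interval for a SAR parameter given eigenvalues
.admissible_interval <- function(ev) {
  emin <- min(ev); emax <- max(ev)
  .assert(emin < 0 && emax > 0,
          "weight matrix eigenvalues do not bracket zero; no admissible interval")
  c(1 / emin, 1 / emax)
}
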