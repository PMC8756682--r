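#' Ordered areal units with polygon geometry
#'
#' A `spatial_frame` is the spatial support for every downstream computation:
#' an ordered set of areal units (districts), each with a polygon or
#' multipolygon geometry given as a list of closed rings. The unit order is
#' stable and defines the row/column order of every weight matrix and
#' variable vector in the analysis.
#'
#' @param ids character vector of unique unit identifiers.
#' @param geoms list (one element per unit) of lists of rings; each ring is a
#'   two-column numeric matrix of (lon, lat) vertices whose first and last
#'   rows coincide and which has at least 4 rows (3 distinct vertices).
#'   Multipolygon units are represented as several rings in the same list.
#' @param display_names optional character vector of human-readable names.
#'
#' @return An object of class `spatial_frame` with elements `ids`, `geoms`
#'   and `display_names`.
#' @export
spatial_frame <- function(ids, geoms, display_names = NULL) {
  .assert(length(ids) >= 1, "a spatial frame needs at least one unit")
  ids <- as.character(ids)
  .assert(!anyNA(ids) && all(nzchar(ids)), "unit ids must be non-missing")
  .assert(!anyDuplicated(ids),
          "duplicate unit ids: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  .assert(is.list(geoms) && length(geoms) == length(ids),
          "geoms must be a list with one element per unit")
  for (u in seq_along(geoms)) {
    rings <- geoms[[u]]
    .assert(is.list(rings) && length(rings) >= 1,
            "unit ", ids[u], ": geometry must contain at least one ring")
    for (r in seq_along(rings)) {
      ring <- rings[[r]]
      .assert(is.matrix(ring) && ncol(ring) == 2 && is.numeric(ring),
              "unit ", ids[u], ": ring ", r,
              " must be a two-column numeric matrix")
      .assert(nrow(ring) >= 4,
              "unit ", ids[u], ": ring ", r, " has fewer than 4 vertices")
      .assert(all(is.finite(ring)),
              "unit ", ids[u], ": ring ", r, " has non-finite coordinates")
      .assert(all(ring[1, ] == ring[nrow(ring), ]),
              "unit ", ids[u], ": ring ", r,
              " is not closed (first vertex must equal last)")
      geoms[[u]][[r]] <- unname(ring)
    }
  }
  if (!is.null(display_names)) {
    .assert(length(display_names) == length(ids),
            "display_names must match ids in length")
    display_names <- as.character(display_names)
  }
  structure(list(ids = ids, geoms = geoms, display_names = display_names),
            class = "spatial_frame")
}

#' Number of areal units in a spatial frame
#' @param frame a [spatial_frame()].
#' @return integer unit count.
#' @export
n_units <- function(frame) {
  stopifnot(inherits(frame, "spatial_frame"))
  length(frame$ids)
}

#' @export
print.spatial_frame <- function(x, ...) {
  nr <- sum(vapply(x$geoms, length, 1L))
  cat("<spatial_frame> ", length(x$ids), " units, ", nr, " rings\n", sep = "")
  cat("  ids: ", paste(utils::head(x$ids, 6), collapse = ", "),
      if (length(x$ids) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# bounding box per unit: matrix n x 4 (xmin, ymin, xmax, ymax)
.unit_bboxes <- function(frame) {
  t(vapply(frame$geoms, function(rings) {
    xy <- do.call(rbind, rings)
    c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
  }, numeric(4)))
}

# signed shoelace area summed over rings (absolute value per ring)
.unit_area <- function(rings) {
  sum(vapply(rings, function(r) {
    x <- r[-nrow(r), 1]; y <- r[-nrow(r), 2]
    abs(sum(x * (y[c(2:length(y), 1)]) - x[c(2:length(x), 1)] * y)) / 2
  }, numeric(1)))
}
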