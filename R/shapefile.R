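# Minimal ESRI shapefile polygon codec (shape type 5), written against the
# public format description: big-endian file header fields, little-endian
# record payloads, ring vertex lists stored as parts. The attribute side
# (.dbf) goes through the foreign package. Only what the pipeline needs is
# implemented: polygon records and a string id column.

.SHP_POLYGON <- 5L

.read_shapefile <- function(path, id_field) {
  shp <- path
  base <- sub("\\.shp$", "", shp, ignore.case = TRUE)
  dbf <- paste0(base, ".dbf")
  .assert(file.exists(shp), "file not found: ", shp)
  .assert(file.exists(dbf), "missing attribute file: ", dbf)

  con <- file(shp, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  .assert(identical(magic, 9994L), shp, " is not a shapefile")
  invisible(readBin(con, "integer", 5, size = 4, endian = "big"))
  file_len_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  .assert(identical(version, 1000L), "unsupported shapefile version")
  shape_type <- readBin(con, "integer", 1, size = 4, endian = "little")
  .assert(shape_type == .SHP_POLYGON,
          "unsupported shape type ", shape_type, " (only polygons)")
  invisible(readBin(con, "double", 8, size = 8, endian = "little")) # bbox+z+m

  geoms <- list()
  bytes_read <- 100L
  total_bytes <- file_len_words * 2L
  while (bytes_read < total_bytes) {
    rec_head <- readBin(con, "integer", 2, size = 4, endian = "big")
    if (length(rec_head) < 2) break
    content_words <- rec_head[2]
    rtype <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (rtype == 0L) {                      # null shape
      geoms[[length(geoms) + 1L]] <- NULL
      bytes_read <- bytes_read + 8L + content_words * 2L
      next
    }
    .assert(rtype == .SHP_POLYGON, "record ", length(geoms) + 1,
            " has unsupported shape type ", rtype)
    invisible(readBin(con, "double", 4, size = 8, endian = "little")) # bbox
    num_parts <- readBin(con, "integer", 1, size = 4, endian = "little")
    num_points <- readBin(con, "integer", 1, size = 4, endian = "little")
    parts <- readBin(con, "integer", num_parts, size = 4, endian = "little")
    pts <- readBin(con, "double", 2 * num_points, size = 8, endian = "little")
    xy <- matrix(pts, ncol = 2, byrow = TRUE)
    starts <- parts + 1L
    ends <- c(parts[-1], num_points)
    rings <- lapply(seq_len(num_parts), function(p)
      xy[starts[p]:ends[p], , drop = FALSE])
    geoms[[length(geoms) + 1L]] <- rings
    bytes_read <- bytes_read + 8L + content_words * 2L
  }
  .assert(length(geoms) > 0, shp, " contains no records")

  attrs <- foreign::read.dbf(dbf, as.is = TRUE)
  .assert(id_field %in% names(attrs),
          "id field '", id_field, "' not in ", dbf)
  .assert(nrow(attrs) == length(geoms), "dbf has ", nrow(attrs),
          " rows for ", length(geoms), " shapes")
  ids <- as.character(attrs[[id_field]])
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0, "duplicate id '", dup[1], "' at feature ",
          which(ids == dup[1])[2])
  nm <- if ("disp_name" %in% names(attrs)) as.character(attrs$disp_name) else NULL
  spatial_frame(ids, geoms, nm)
}

#' Write a spatial frame as an ESRI shapefile
#'
#' Emits `.shp`, `.shx` and `.dbf` (ids as a string column named by
#' `id_field`, truncated to the 10-character dbf field-name limit). Each unit
#' becomes one polygon record whose parts are the unit's rings, coordinates
#' unchanged, so a write-read round trip reproduces the frame.
#'
#' @param frame a [spatial_frame()].
#' @param path output path ending in `.shp`.
#' @param id_field dbf column name for the unit id.
#' @return the `.shp` path, invisibly.
#' @export
write_shapefile <- function(frame, path, id_field = "unit_id") {
  stopifnot(inherits(frame, "spatial_frame"))
  .assert(grepl("\\.shp$", path, ignore.case = TRUE),
          "shapefile path must end in .shp")
  base <- sub("\\.shp$", "", path, ignore.case = TRUE)
  n <- n_units(frame)

  records <- lapply(seq_len(n), function(k) {
    rings <- frame$geoms[[k]]
    xy <- do.call(rbind, rings)
    npts <- vapply(rings, nrow, 1L)
    parts <- cumsum(c(0L, npts[-length(npts)]))
    list(bbox = c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2])),
         parts = as.integer(parts), xy = xy)
  })
  content_words <- vapply(records, function(r) {
    # shape type + bbox + counts + parts + points, in 16-bit words
    (4L + 32L + 8L + 4L * length(r$parts) + 16L * nrow(r$xy)) %/% 2L
  }, integer(1))
  all_xy <- do.call(rbind, lapply(records, `[[`, "xy"))
  gbox <- c(min(all_xy[, 1]), min(all_xy[, 2]),
            max(all_xy[, 1]), max(all_xy[, 2]))
  total_words <- 50L + sum(4L + content_words)

  .write_shp_header <- function(con, words) {
    writeBin(9994L, con, size = 4, endian = "big")
    writeBin(integer(5), con, size = 4, endian = "big")
    writeBin(as.integer(words), con, size = 4, endian = "big")
    writeBin(1000L, con, size = 4, endian = "little")
    writeBin(.SHP_POLYGON, con, size = 4, endian = "little")
    writeBin(c(gbox, 0, 0, 0, 0), con, size = 8, endian = "little")
  }

  con <- file(paste0(base, ".shp"), "wb")
  .write_shp_header(con, total_words)
  for (k in seq_len(n)) {
    r <- records[[k]]
    writeBin(as.integer(k), con, size = 4, endian = "big")
    writeBin(content_words[k], con, size = 4, endian = "big")
    writeBin(.SHP_POLYGON, con, size = 4, endian = "little")
    writeBin(r$bbox, con, size = 8, endian = "little")
    writeBin(length(r$parts), con, size = 4, endian = "little")
    writeBin(nrow(r$xy), con, size = 4, endian = "little")
    writeBin(r$parts, con, size = 4, endian = "little")
    writeBin(as.numeric(t(r$xy)), con, size = 8, endian = "little")
  }
  close(con)

  # .shx index: same header (its own length), then offset/length per record
  con <- file(paste0(base, ".shx"), "wb")
  .write_shp_header(con, 50L + 4L * n)
  offset <- 50L
  for (k in seq_len(n)) {
    writeBin(offset, con, size = 4, endian = "big")
    writeBin(content_words[k], con, size = 4, endian = "big")
    offset <- offset + 4L + content_words[k]
  }
  close(con)

  dbf_field <- substr(id_field, 1, 10)
  attrs <- data.frame(a = frame$ids, stringsAsFactors = FALSE)
  names(attrs) <- dbf_field
  if (!is.null(frame$display_names)) {
    attrs$disp_name <- frame$display_names
  }
  foreign::write.dbf(attrs, paste0(base, ".dbf"))
  invisible(paste0(base, ".shp"))
}
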