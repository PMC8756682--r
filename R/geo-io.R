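# Reading and writing the external formats the pipeline touches: GeoJSON and
# shapefile polygons, CSV attribute tables, GAL contiguity files, and the
# LISA-labelled GeoJSON map layers.

#' Read areal-unit polygons
#'
#' Reads a GeoJSON FeatureCollection (RFC 7946) or an ESRI shapefile into a
#' [spatial_frame()], preserving file order. Multipolygon geometries are kept
#' as multiple rings of the same unit; coordinates are passed through
#' unchanged (contiguity is topological, so no projection is applied).
#'
#' @param path file path (`.geojson`/`.json`, or the `.shp` of a shapefile).
#' @param id_field name of the feature property (or dbf column) holding the
#'   unit id; must be present and unique on every feature.
#' @param format `"geojson"` or `"shapefile"`; guessed from the extension by
#'   default.
#' @return a [spatial_frame()] in file order.
#' @export
read_polygons <- function(path, id_field = "unit_id",
                          format = c("auto", "geojson", "shapefile")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.shp$", path, ignore.case = TRUE))
      "shapefile" else "geojson"
  }
  if (format == "geojson") .read_geojson(path, id_field)
  else .read_shapefile(path, id_field)
}

.ring_from_coords <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) as.numeric(p[1:2])))
  unname(m)
}

.read_geojson <- function(path, id_field) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .assert(identical(gj$type, "FeatureCollection"),
          path, " is not a GeoJSON FeatureCollection")
  feats <- gj$features
  .assert(length(feats) > 0, path, " contains no features")
  ids <- character(length(feats))
  geoms <- vector("list", length(feats))
  names_out <- rep(NA_character_, length(feats))
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    props <- f$properties
    .assert(!is.null(props[[id_field]]),
            "feature ", k, " lacks id field '", id_field, "'")
    ids[k] <- as.character(props[[id_field]])
    if (!is.null(props$display_name)) names_out[k] <- as.character(props$display_name)
    g <- f$geometry
    .assert(!is.null(g$type), "feature ", k, " has no geometry")
    rings <- switch(
      g$type,
      Polygon = lapply(g$coordinates, .ring_from_coords),
      MultiPolygon = unlist(lapply(g$coordinates, function(poly)
        lapply(poly, .ring_from_coords)), recursive = FALSE),
      .assert(FALSE, "feature ", k, " has unsupported geometry type ", g$type)
    )
    geoms[[k]] <- rings
  }
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0, "duplicate id '", dup[1], "' at feature ",
          which(ids == dup[1])[2])
  spatial_frame(ids, geoms,
                if (all(is.na(names_out))) NULL else names_out)
}

#' Write a spatial frame as GeoJSON
#'
#' Serialises the units as a FeatureCollection, one Polygon feature per unit
#' carrying its rings, with `id_field` (plus optional extra columns) as
#' feature properties. Reading the output back with [read_polygons()]
#' reproduces ids, order and ring vertices.
#'
#' @param frame a [spatial_frame()].
#' @param path output path.
#' @param id_field property name for the unit id.
#' @param properties optional data frame of extra per-unit properties
#'   (frame order).
#' @return the path, invisibly.
#' @export
write_polygons_geojson <- function(frame, path, id_field = "unit_id",
                                   properties = NULL) {
  stopifnot(inherits(frame, "spatial_frame"))
  if (!is.null(properties)) {
    .assert(nrow(properties) == n_units(frame),
            "properties has ", nrow(properties), " rows for ",
            n_units(frame), " units")
  }
  feats <- lapply(seq_along(frame$ids), function(k) {
    props <- list()
    props[[id_field]] <- frame$ids[k]
    if (!is.null(frame$display_names) && !is.na(frame$display_names[k])) {
      props$display_name <- frame$display_names[k]
    }
    if (!is.null(properties)) {
      for (col in names(properties)) {
        props[[col]] <- properties[k, col]
      }
    }
    list(type = "Feature",
         properties = props,
         geometry = list(
           type = "Polygon",
           coordinates = lapply(frame$geoms[[k]], function(ring)
             lapply(seq_len(nrow(ring)), function(r) ring[r, ]))
         ))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a district attribute table from CSV
#'
#' Parses a CSV with a header row into an attribute table: the `id_field`
#' column gives the unit ids, every other column is parsed as a numeric
#' variable. Percent variables are validated to lie in \[0, 100\] unless
#' `range_check = FALSE` (the check catches proportion-vs-percent unit
#' errors early).
#'
#' @param path CSV path.
#' @param id_field id column name.
#' @param range_check validate variables to \[0, 100\]?
#' @return data frame with `unit_id` first, then numeric variable columns.
#' @export
read_attributes <- function(path, id_field = "unit_id", range_check = TRUE) {
  .assert(file.exists(path), "file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .assert(id_field %in% names(raw), "id column '", id_field, "' not in ", path)
  ids <- raw[[id_field]]
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0, "duplicate unit id '", dup[1], "' in ", path)
  out <- data.frame(unit_id = ids, stringsAsFactors = FALSE)
  for (col in setdiff(names(raw), id_field)) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    .assert(length(bad) == 0, "non-numeric value '", raw[[col]][bad[1]],
            "' in column '", col, "', row ", bad[1])
    .assert(!anyNA(v), "missing value in column '", col, "', row ",
            which(is.na(v))[1])
    if (range_check) {
      oob <- which(v < 0 | v > 100)
      .assert(length(oob) == 0, "value ", v[oob[1]], " in column '", col,
              "', row ", oob[1], " outside [0, 100]; percent scale expected ",
              "(use range_check = FALSE to disable)")
    }
    out[[col]] <- v
  }
  out
}

#' Write an attribute table as CSV
#'
#' Numeric values are printed with enough digits (15 significant) that a
#' write-read round trip reproduces them to printed precision.
#'
#' @param table attribute data frame with a `unit_id` column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_attributes <- function(table, path) {
  out <- table
  for (col in setdiff(names(out), "unit_id")) {
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align an attribute table to a spatial frame
#'
#' Reorders the table rows into frame order so that variable vectors
#' index-match the weight matrix. Values are never changed, only order; the
#' id sets must coincide exactly.
#'
#' @param frame a [spatial_frame()].
#' @param table attribute data frame with a `unit_id` column.
#' @return the table reordered to frame order.
#' @export
align_attributes <- function(frame, table) {
  stopifnot(inherits(frame, "spatial_frame"))
  .assert("unit_id" %in% names(table), "table lacks a unit_id column")
  missing_in_table <- setdiff(frame$ids, table$unit_id)
  .assert(length(missing_in_table) == 0, "ids in frame missing from table: ",
          paste(missing_in_table, collapse = ", "))
  extra <- setdiff(table$unit_id, frame$ids)
  .assert(length(extra) == 0, "ids in table missing from frame: ",
          paste(extra, collapse = ", "))
  out <- table[match(frame$ids, table$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- GAL contiguity exchange format ----------------------------------------

#' Write binary contiguity weights as a GAL file
#'
#' GAL dialect: a header line `0 n units unit_id`, then for each unit a line
#' `<id> <k>` followed by a line with its k neighbor ids (blank for
#' islands). Only binary weights can be serialised this way.
#'
#' @param weights binary `spatial_weights`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gal <- function(weights, path) {
  stopifnot(inherits(weights, "spatial_weights"))
  .assert(weights$style == "binary", "GAL stores binary weights only")
  nb <- neighbor_sets(weights)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("0", weights$n, "units", "unit_id"), con)
  for (id in weights$ids) {
    writeLines(paste(id, length(nb[[id]])), con)
    writeLines(paste(nb[[id]], collapse = " "), con)
  }
  invisible(path)
}

#' Read a GAL contiguity file
#'
#' @param path GAL path.
#' @param frame the [spatial_frame()] the weights refer to; the header count
#'   must match its unit count and every id must be known.
#' @return binary `spatial_weights` in frame order.
#' @export
read_gal <- function(path, frame) {
  stopifnot(inherits(frame, "spatial_frame"))
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  .assert(length(lines) >= 1, "empty GAL file")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  .assert(length(header) >= 2, "malformed GAL header")
  n_declared <- suppressWarnings(as.integer(header[2]))
  .assert(!is.na(n_declared), "malformed GAL header count")
  .assert(n_declared == n_units(frame), "GAL declares ", n_declared,
          " units but the frame has ", n_units(frame))
  pairs_a <- character(0); pairs_b <- character(0)
  ln <- 2L
  seen <- character(0)
  for (u in seq_len(n_declared)) {
    .assert(ln <= length(lines), "GAL body ends early: expected ",
            n_declared, " units, found ", u - 1)
    head_u <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    .assert(length(head_u) == 2, "malformed GAL unit header at line ", ln)
    id <- head_u[1]
    k <- suppressWarnings(as.integer(head_u[2]))
    .assert(!is.na(k) && k >= 0, "malformed neighbor count at line ", ln)
    .assert(id %in% frame$ids, "unknown unit id '", id, "' at line ", ln)
    nbrs <- if (ln + 1L <= length(lines))
      strsplit(trimws(lines[ln + 1L]), "\\s+")[[1]] else character(0)
    nbrs <- nbrs[nzchar(nbrs)]
    .assert(length(nbrs) == k, "unit '", id, "' declares ", k,
            " neighbors but lists ", length(nbrs))
    unknown <- setdiff(nbrs, frame$ids)
    .assert(length(unknown) == 0, "unknown neighbor ids for '", id, "': ",
            paste(unknown, collapse = ", "))
    pairs_a <- c(pairs_a, rep(id, k)); pairs_b <- c(pairs_b, nbrs)
    seen <- c(seen, id)
    ln <- ln + 2L
  }
  .assert(!anyDuplicated(seen), "duplicate unit in GAL body")
  leftover <- lines[seq.int(ln, length.out = max(0, length(lines) - ln + 1))]
  .assert(all(!nzchar(trimws(leftover))), "GAL body longer than declared")
  if (length(pairs_a) == 0) {
    from_adjacency_pairs(frame$ids, NULL)
  } else {
    from_adjacency_pairs(frame$ids, cbind(pairs_a, pairs_b))
  }
}

#' Write a LISA map layer as GeoJSON
#'
#' One feature per unit with the five cluster properties `unit_id`,
#' `local_i`, `quadrant`, `pseudo_p`, `cluster_label` and the unchanged
#' geometry -- the serialised form of a LISA cluster map.
#'
#' @param frame a [spatial_frame()].
#' @param stats a `local_moran` result indexed like the frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_lisa_geojson <- function(frame, stats, path) {
  stopifnot(inherits(frame, "spatial_frame"), inherits(stats, "local_moran"))
  .assert(nrow(stats) == n_units(frame), "stats has ", nrow(stats),
          " rows for ", n_units(frame), " units")
  .assert(identical(as.character(stats$unit_id), frame$ids),
          "stats unit ids do not match the frame")
  props <- data.frame(
    local_i = stats$local_i,
    quadrant = stats$quadrant,
    pseudo_p = stats$pseudo_p,
    cluster_label = stats$cluster_label,
    stringsAsFactors = FALSE
  )
  write_polygons_geojson(frame, path, id_field = "unit_id",
                         properties = props)
}
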