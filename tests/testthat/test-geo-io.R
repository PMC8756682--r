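test_that("GeoJSON polygons round trip with ids, order and vertices intact", {
  f <- squares_frame(c("A", "B", "C", "D"),
                     rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_polygons_geojson(f, path)
  f2 <- read_polygons(path)
  expect_equal(f2$ids, c("A", "B", "C", "D"))
  expect_equal(f2$geoms, f$geoms)

  # duplicate ids are rejected with the offending feature named
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$features[[2]]$properties$unit_id <- "A"
  dup_path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, dup_path, auto_unbox = TRUE, digits = NA)
  expect_error(read_polygons(dup_path), "duplicate id 'A'")

  # missing id field names the feature index
  gj$features[[3]]$properties <- list(other = 1)
  bad_path <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, bad_path, auto_unbox = TRUE, digits = NA)
  expect_error(read_polygons(bad_path), "feature 3")
})

test_that("a shapefile write-read reproduces the GeoJSON read exactly", {
  f <- make_grid_frame(3, 4)
  gj <- withr::local_tempfile(fileext = ".geojson")
  shp <- withr::local_tempfile(fileext = ".shp")
  write_polygons_geojson(f, gj)
  write_shapefile(f, shp)
  from_gj <- read_polygons(gj)
  from_shp <- read_polygons(shp, format = "shapefile")
  expect_equal(from_shp$ids, from_gj$ids)
  expect_equal(from_shp$geoms, from_gj$geoms)
})

test_that("attribute CSVs parse, validate and report offending cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("id,sba\nA,50\nB,70", p)
  tab <- read_attributes(p, id_field = "id")
  expect_equal(tab$unit_id, c("A", "B"))
  expect_equal(tab$sba, c(50, 70))

  writeLines("id,sba\nA,n/a\nB,70", p)
  expect_error(read_attributes(p, id_field = "id"), "n/a")
  writeLines("id,sba\nA,50\nA,70", p)
  expect_error(read_attributes(p, id_field = "id"), "duplicate")
  writeLines("id,sba\nA,150\nB,70", p)
  expect_error(read_attributes(p, id_field = "id"), "\\[0, 100\\]")
  expect_equal(read_attributes(p, id_field = "id", range_check = FALSE)$sba,
               c(150, 70))
})

test_that("the study-scale attribute table survives a write-read round trip", {
  sc <- get_paper_scenario()
  p <- withr::local_tempfile(fileext = ".csv")
  write_attributes(sc$table, p)
  back <- read_attributes(p)
  expect_equal(back$unit_id, sc$table$unit_id)
  expect_lt(max(abs(as.matrix(back[, -1]) - as.matrix(sc$table[, -1]))), 1e-9)
})

test_that("alignment reorders rows to frame order without touching values", {
  f <- squares_frame(c("B", "A"), rbind(c(0, 0), c(1, 0)))
  tab <- data.frame(unit_id = c("A", "B"), v = c(1, 2))
  out <- align_attributes(f, tab)
  expect_equal(out$unit_id, c("B", "A"))
  expect_equal(out$v, c(2, 1))
  expect_equal(align_attributes(f, out), out)
  expect_error(
    align_attributes(squares_frame(c("A", "B", "C"),
                                   rbind(c(0, 0), c(1, 0), c(2, 0))), tab),
    "C")
})

test_that("GAL files list neighbors per unit and round trip exactly", {
  f <- make_grid_frame(2, 2)
  W <- shared_border_adjacency(f)  # the 4-cycle: 2 neighbors each
  p <- withr::local_tempfile(fileext = ".gal")
  write_gal(W, p)
  lines <- readLines(p)
  expect_match(lines[1], "^0 4 ")
  counts <- as.integer(vapply(strsplit(lines[seq(2, 8, by = 2)], " "),
                              `[`, "", 2))
  expect_equal(counts, rep(2L, 4))
  expect_equal(neighbor_sets(read_gal(p, f)), neighbor_sets(W))

  f8 <- make_grid_frame(8, 8)
  W8 <- queen_adjacency(f8)
  p8 <- withr::local_tempfile(fileext = ".gal")
  write_gal(W8, p8)
  expect_equal(neighbor_sets(read_gal(p8, f8)), neighbor_sets(W8))

  # header count must match the frame
  writeLines(c("0 5 units unit_id", lines[-1]), p)
  expect_error(read_gal(p, f), "declares 5")
  expect_error(write_gal(row_standardize(W), p), "binary")
})

test_that("LISA layers serialise the five cluster properties and re-read cleanly", {
  base <- make_grid_frame(4, 4)
  corners <- cbind(c(rep(0:3, 4), 20), c(rep(0:3, each = 4), 20))
  f <- squares_frame(c(base$ids, "far"), corners)
  W <- row_standardize(queen_adjacency(f))
  x <- c(rep(c(10, 90), each = 8), 50) + seq(0, 1.6, by = 0.1)
  st <- local_moran(W, x, permutations = 199, seed = 3)
  p <- withr::local_tempfile(fileext = ".geojson")
  write_lisa_geojson(f, st, p)
  back <- read_polygons(p)
  expect_equal(back$ids, f$ids)

  gj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  props <- gj$features[[1]]$properties
  expect_true(all(c("unit_id", "local_i", "quadrant", "pseudo_p",
                    "cluster_label") %in% names(props)))
  labels <- vapply(gj$features, function(ft)
    ft$properties$cluster_label, "")
  expect_true(all(labels %in% c("hotspot", "coldspot", "high_low_outlier",
                                "low_high_outlier", "not_significant",
                                "island")))
  expect_equal(labels[17], "island")

  st3 <- st[1:3, ]
  expect_error(write_lisa_geojson(f, st3, p), "3 rows")
})
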