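test_that("GeoJSON write/read round-trips features, ids, tags, geometry", {
  fc <- tagged_features(list(
    square_feature("a", 0, 0, 90, 90, c(landuse = "residential")),
    square_feature("b", 120, 0, 210.123456789, 90, c(building = "yes",
                                                     height = "12")),
    line_feature("c", rbind(c(0, 200), c(500, 200), c(500, 700)),
                 c(highway = "primary", lanes = "3"))
  ), test_crs)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_features(fc, path)
  polys <- read_features(path, "polygons")
  lines <- read_features(path, "lines")
  expect_equal(length(polys), 2L)
  expect_equal(length(lines), 1L)
  expect_equal(polys$crs, test_crs)
  back <- c(polys$features, lines$features)
  names(back) <- vapply(back, function(f) f$id, "")
  for (f in fc$features) {
    g0 <- f$geometry
    g1 <- back[[f$id]]$geometry
    expect_identical(back[[f$id]]$tags, f$tags)
    if (g0$type == "polygon") {
      expect_lt(max(abs(g0$parts[[1]][[1]] - g1$parts[[1]][[1]])), 1e-9)
    } else {
      expect_lt(max(abs(g0$parts[[1]] - g1$parts[[1]])), 1e-9)
    }
  }
})

test_that("empty collections and geometry-kind filtering behave", {
  fc <- tagged_features(list(), test_crs)
  path <- withr::local_tempfile(fileext = ".geojson")
  write_features(fc, path)
  expect_equal(length(read_features(path, "polygons")), 0L)

  fc2 <- tagged_features(list(
    square_feature("p", 0, 0, 60, 60, c(landuse = "residential"))), test_crs)
  write_features(fc2, path)
  expect_equal(length(read_features(path, "lines")), 0L)
})

test_that("packed auxiliary tags unpack; explicit columns win collisions", {
  expect_identical(unpack_tags('"leisure"=>"park"'),
                   c(leisure = "park"))
  expect_identical(unpack_tags('"a"=>"1","b"=>"x y"'),
                   c(a = "1", b = "x y"))
  path <- withr::local_tempfile(fileext = ".geojson")
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = test_crs)),
    features = list(list(
      type = "Feature",
      properties = list(id = "f1", landuse = "residential",
                        other_tags = '"leisure"=>"park","landuse"=>"forest"'),
      geometry = list(type = "Polygon", coordinates = list(
        list(c(0, 0), c(60, 0), c(60, 60), c(0, 60), c(0, 0))))
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  fc <- read_features(path, "polygons")
  tags <- fc$features[[1]]$tags
  expect_equal(tags[["leisure"]], "park")
  expect_equal(tags[["landuse"]], "residential")  # column beats packed value
})

test_that("multi-geometries explode into parts sharing the parent id", {
  path <- withr::local_tempfile(fileext = ".geojson")
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = test_crs)),
    features = list(list(
      type = "Feature", properties = list(id = "m"),
      geometry = list(type = "MultiPolygon", coordinates = list(
        list(list(c(0, 0), c(60, 0), c(60, 60), c(0, 60), c(0, 0))),
        list(list(c(100, 0), c(160, 0), c(160, 60), c(100, 60), c(100, 0)))
      ))
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  fc <- read_features(path, "polygons")
  expect_equal(vapply(fc$features, function(f) f$id, ""), c("m#1", "m#2"))
})

test_that("missing or geographic CRS is rejected with guidance", {
  path <- withr::local_tempfile(fileext = ".geojson")
  obj <- list(type = "FeatureCollection", features = list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  expect_error(read_features(path, "polygons"), "declare")
  expect_error(read_features(path, "polygons", crs = "EPSG:4326"),
               "geographic")
  expect_error(read_features("definitely_not_there.geojson", "polygons"),
               "no such file")
})

test_that("clip_to_bbox keeps, drops and trims correctly and is idempotent", {
  fc <- tagged_features(list(
    square_feature("in", 10, 10, 100, 100, c(landuse = "residential")),
    square_feature("out", 900, 900, 960, 960, c(landuse = "commercial")),
    line_feature("cross", rbind(c(-50, 50), c(150, 50)), c(highway = "service"))
  ), test_crs)
  bb <- c(0, 0, 200, 200)

  all_in <- clip_to_bbox(fc, c(-100, -100, 1000, 1000))
  expect_equal(length(all_in), 3L)
  expect_equal(all_in$features[[1]]$geometry$parts[[1]][[1]],
               fc$features[[1]]$geometry$parts[[1]][[1]])

  clipped <- clip_to_bbox(fc, bb)
  expect_equal(vapply(clipped$features, function(f) f$id, ""),
               c("in", "cross"))
  # independent length: the segment (-50,50)-(150,50) has 150 m inside x>=0
  ln <- clipped$features[[2]]$geometry
  expect_equal(geom_length <- urbanmosaic:::geom_length(ln), 150)

  twice <- clip_to_bbox(clipped, bb)
  expect_equal(lapply(twice$features, `[[`, "geometry"),
               lapply(clipped$features, `[[`, "geometry"))

  expect_equal(length(clip_to_bbox(fc, c(2000, 2000, 3000, 3000))), 0L)
  expect_error(clip_to_bbox(fc, c(0, 0, 0, 100)), "degenerate")
})

test_that("polygon clipping area matches an interval-arithmetic oracle", {
  # axis-aligned rectangle clipped by a rectangle: overlap area is closed form
  set.seed(41)
  for (i in 1:20) {
    r1 <- sort(runif(2, 0, 500)); r2 <- sort(runif(2, 0, 500))
    f <- square_feature("r", r1[1], r2[1], r1[2], r2[2], character())
    bb <- c(100, 100, 400, 400)
    ov_x <- max(0, min(r1[2], 400) - max(r1[1], 100))
    ov_y <- max(0, min(r2[2], 400) - max(r2[1], 100))
    cl <- clip_to_bbox(tagged_features(list(f), test_crs), bb)
    got <- if (length(cl)) urbanmosaic:::geom_area(cl$features[[1]]$geometry)
           else 0
    expect_equal(got, ov_x * ov_y, tolerance = 1e-9)
  }
})

test_that("raster ASCII round trip is bit-identical", {
  r <- mk_raster(matrix(c(1L, 2L, 0L, 3L), 2))
  path <- withr::local_tempfile(fileext = ".asc")
  write_raster(r, path)
  back <- read_raster(path)
  expect_identical(back$values, r$values)
  expect_equal(back$xmin, r$xmin)
  expect_equal(back$ymax, r$ymax)
  expect_equal(back$cell, r$cell)
  expect_identical(back$nodata, r$nodata)
  expect_equal(back$crs, r$crs)

  # all-nodata raster preserved
  r0 <- mk_raster(matrix(0L, 3, 4))
  write_raster(r0, path)
  expect_identical(read_raster(path)$values, r0$values)

  # random legend-coded raster
  set.seed(7)
  v <- matrix(sample(0:27, 2500, replace = TRUE), 50)
  rr <- mk_raster(v)
  write_raster(rr, path)
  expect_identical(read_raster(path)$values, rr$values)

  # continuous raster with NA
  rn <- mk_num_raster(matrix(c(0.123456789012345, NA, -5, 1e6), 2))
  write_raster(rn, path)
  bn <- read_raster(path)
  expect_identical(bn$values, rn$values)
})

test_that("legend colliding with nodata is refused", {
  expect_error(
    cat_raster(matrix(1L, 2, 2), 0, 60, 30, test_crs, nodata = 1L,
               legend = c("1" = "forest")),
    "collides")
})
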