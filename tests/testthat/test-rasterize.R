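test_that("rasterization codes exactly the cells whose centers are covered", {
  grid <- grid_spec(c(0, 0, 300, 300), 30, test_crs)

  # polygon covering the whole grid
  fc <- tagged_features(list(
    square_feature("all", -10, -10, 310, 310, character())), test_crs)
  r <- rasterize_class(fc, grid, 13L)
  expect_true(all(r$values == 13L))

  # empty collection -> all nodata
  r0 <- rasterize_class(tagged_features(list(), test_crs), grid, 13L)
  expect_true(all(r0$values == 0L))

  # 90x90 m square exactly over a 3x3 block of cells
  fc3 <- tagged_features(list(
    square_feature("sq", 30, 30, 120, 120, character())), test_crs)
  r3 <- rasterize_class(fc3, grid, 5L)
  expect_equal(sum(r3$values == 5L), 9L)

  # brute-force point-in-polygon oracle over every cell center
  set.seed(23)
  poly <- geom_polygon(rbind(c(35, 20), c(250, 60), c(280, 270), c(90, 220),
                             c(35, 20)))
  fcp <- tagged_features(list(tagged_feature("p", poly)), test_crs)
  rp <- rasterize_class(fcp, grid, 9L)
  xs <- 0 + (1:10 - 0.5) * 30
  ys <- 300 - (1:10 - 0.5) * 30
  for (i in 1:10) for (j in 1:10) {
    inside <- urbanmosaic:::points_in_rings(xs[j], ys[i],
                                            poly$parts[[1]])
    expect_identical(rp$values[i, j] == 9L, as.logical(inside))
  }
})

test_that("CRS mismatch between grid and features errors", {
  grid <- grid_spec(c(0, 0, 300, 300), 30, "EPSG:32617")
  fc <- tagged_features(list(
    square_feature("a", 0, 0, 60, 60, character())), test_crs)
  expect_error(rasterize_class(fc, grid, 1L), "CRS")
})

test_that("merge picks the highest-priority code per cell", {
  reg <- default_registry()
  # open-green (10) vs primary road (16): infrastructure wins
  g <- matrix(10L, 4, 4)
  p <- matrix(0L, 4, 4); p[2, ] <- 16L
  merged <- merge_layers(list("10" = mk_raster(g), "16" = mk_raster(p)), reg)
  expect_true(all(merged$values[2, ] == 16L))
  expect_true(all(merged$values[-2, ] == 10L))

  # single mask passes through
  one <- merge_layers(list("10" = mk_raster(g)), reg)
  expect_identical(one$values, g)

  # per-cell argmax-by-rank oracle on random stacks
  set.seed(77)
  for (rep in 1:10) {
    codes <- sample(registry_codes(reg), 5)
    masks <- random_masks(12, 9, codes)
    merged <- merge_layers(masks, reg)
    ranks <- reg$priority[as.character(codes)]
    for (cell in sample(12 * 9, 20)) {
      on <- codes[vapply(masks, function(m) m$values[cell] != 0L, TRUE)]
      want <- if (!length(on)) 0L else on[which.max(reg$priority[as.character(on)])]
      expect_identical(merged$values[cell], as.integer(want))
    }
    # output codes never leave the input set
    expect_true(all(merged$values %in% c(0L, codes)))
  }
})

test_that("merging refuses mismatched grids and unranked classes", {
  reg <- default_registry()
  a <- mk_raster(matrix(1L, 3, 3))
  b <- mk_raster(matrix(2L, 4, 4))
  expect_error(merge_layers(list("1" = a, "2" = b), reg), "same grid")
  expect_error(merge_layers(list("99" = a), reg), "priority")
})

test_that("promoting a class rank never costs it cells", {
  reg <- default_registry()
  set.seed(13)
  masks <- random_masks(15, 15, c(9L, 13L, 16L))
  base <- merge_layers(masks, reg)
  # promote low vegetation (9) to the top rank
  reg2 <- reg
  reg2$priority[["9"]] <- max(reg$priority) + 1L
  high <- merge_layers(masks, reg2)
  was9 <- base$values == 9L
  expect_true(all(high$values[was9] == 9L))
})

test_that("tiled merge is bit-identical to untiled merge", {
  reg <- default_registry()
  set.seed(99)
  codes <- c(8L, 13L, 16L, 23L)
  masks <- random_masks(64, 64, codes)
  ref <- merge_layers(masks, reg)
  for (ts in c(17L, 64L, 100L)) {
    expect_identical(tile_and_merge(masks, reg, ts)$values, ref$values)
  }
  # single mask, any tiling
  one <- masks[2]
  expect_identical(tile_and_merge(one, reg, 7L)$values,
                   merge_layers(one, reg)$values)
  expect_error(tile_and_merge(masks, reg, 0L), ">= 1")
})

test_that("global reclassification is a total cell-wise lookup", {
  set.seed(3)
  v <- matrix(sample(c(1L, 2L, 5L, 17L), 100, replace = TRUE), 10)
  glob <- mk_raster(v)
  m <- default_reclass_map()
  rc <- reclass_global(glob, m$entries, m$developed_codes)
  expect_true(all(rc$values[v == 1L] == 8L))
  expect_true(all(rc$values[v == 17L] == 28L))  # built -> developed unknown

  # permuted legend composed with its inverse recovers the original
  perm <- c("1" = 101L, "2" = 102L, "5" = 105L, "17" = 117L)
  step1 <- reclass_global(glob, perm)
  inv <- c("101" = 1L, "102" = 2L, "105" = 5L, "117" = 17L)
  step2 <- reclass_global(step1, inv)
  expect_identical(step2$values, glob$values)

  expect_error(reclass_global(glob, c("1" = 8L)), "without a reclass entry")
})

test_that("integration backfills exactly the void cells", {
  set.seed(31)
  osm <- mk_raster(matrix(sample(c(0L, 1L, 13L), 144, replace = TRUE,
                                 prob = c(0.5, 0.25, 0.25)), 12))
  glob <- mk_raster(matrix(sample(c(8L, 9L, 28L), 144, replace = TRUE), 12))
  full <- integrate_global(osm, glob)
  void <- osm$values == 0L
  expect_identical(full$values[void], glob$values[void])
  expect_identical(full$values[!void], osm$values[!void])
  expect_equal(sum(full$values == 0L), 0L)

  # degenerate directions
  none <- mk_raster(matrix(0L, 12, 12))
  expect_identical(integrate_global(none, glob)$values, glob$values)
  expect_identical(integrate_global(glob, glob)$values, glob$values)

  # checkerboard selection oracle
  cb <- matrix(0L, 8, 8); cb[(row(cb) + col(cb)) %% 2 == 0] <- 13L
  osm2 <- mk_raster(cb)
  glob2 <- mk_raster(matrix(8L, 8, 8))
  full2 <- integrate_global(osm2, glob2)
  for (cell in seq_len(64)) {
    want <- if (cb[cell] != 0L) cb[cell] else 8L
    expect_identical(full2$values[cell], want)
  }
})

test_that("grid snapping rounds the extent outward to whole cells", {
  g <- grid_spec(c(0, 0, 95, 61), 30, test_crs)
  expect_equal(c(g$ncol, g$nrow), c(4L, 3L))
  expect_equal(g$xmax, 120)
  expect_equal(g$ymax, 90)
  expect_error(grid_spec(c(0, 0, 100, 100), -5, test_crs), "> 0")
})

test_that("nearest-neighbor alignment relocates categorical cells intact", {
  src <- mk_raster(matrix(1:9 %% 3L + 1L, 3), cell = 60)
  grid <- grid_spec(c(0, 0, 180, 180), 30, test_crs)
  out <- align_to_grid(src, grid)
  expect_equal(dim(out$values), c(6L, 6L))
  # each 2x2 block of the 30 m grid equals its 60 m source cell
  for (i in 1:3) for (j in 1:3) {
    block <- out$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    expect_true(all(block == src$values[i, j]))
  }
})
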