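test_that("focal proportion aggregates blocks to coded-cell fractions", {
  full <- mk_raster(matrix(13L, 6, 6))
  expect_true(all(focal_proportion(full, 90)$values == 1))
  empty <- mk_raster(matrix(0L, 6, 6))
  expect_true(all(focal_proportion(empty, 90)$values == 0))

  # 3x3 blocks with a known count per block
  v <- matrix(0L, 6, 6)
  v[1:3, 1:3][1:4] <- 13L          # 4 of 9 coded in the top-left block
  v[4:6, 4:6] <- 13L               # fully coded block
  p <- focal_proportion(mk_raster(v), 90)
  expect_true(all(abs(p$values[1:3, 1:3] - 4 / 9) < 1e-12))
  expect_true(all(p$values[4:6, 4:6] == 1))
  expect_true(all(p$values[1:3, 4:6] == 0))

  expect_error(focal_proportion(full, 45), "multiple")
})

test_that("partial edge blocks use the cells actually present", {
  v <- matrix(0L, 5, 5)
  v[5, ] <- 13L  # the 2-row bottom edge block row is half coded
  p <- focal_proportion(mk_raster(v), 90)
  expect_true(all(abs(p$values[4:5, 1:3] - 3 / 6) < 1e-12))
})

test_that("distance fields are exact Euclidean distances", {
  # target everywhere -> zero everywhere
  all13 <- mk_raster(matrix(13L, 5, 5))
  expect_true(all(distance_to(all13, 13L)$values == 0))

  # single target: distance equals the norm of center offsets
  v <- matrix(0L, 9, 9); v[4, 6] <- 16L
  d <- distance_to(mk_raster(v), 16L)
  xs <- (1:9 - 0.5) * 30
  ys <- 9 * 30 - (1:9 - 0.5) * 30
  set.seed(6)
  for (k in 1:10) {
    i <- sample(9, 1); j <- sample(9, 1)
    expect_equal(d$values[i, j],
                 sqrt((xs[j] - xs[6])^2 + (ys[i] - ys[4])^2),
                 tolerance = 1e-9)
  }

  # two targets: per-cell minimum of the single-target fields
  v1 <- matrix(0L, 8, 8); v1[2, 2] <- 12L
  v2 <- matrix(0L, 8, 8); v2[7, 5] <- 12L
  both <- v1 + v2
  d1 <- distance_to(mk_raster(v1), 12L)
  d2 <- distance_to(mk_raster(v2), 12L)
  db <- distance_to(mk_raster(both), 12L)
  expect_equal(db$values, pmin(d1$values, d2$values), tolerance = 1e-9)

  expect_error(distance_to(mk_raster(matrix(0L, 3, 3)), 12L), "target")
})

test_that("distance transform matches brute force on random rasters", {
  set.seed(17)
  for (rep in 1:5) {
    v <- matrix(0L, 14, 11)
    v[sample(length(v), 5)] <- 15L
    r <- mk_raster(v)
    d <- distance_to(r, 15L)
    xs <- (seq_len(11) - 0.5) * 30
    ys <- 14 * 30 - (seq_len(14) - 0.5) * 30
    tgt <- which(v == 15L, arr.ind = TRUE)
    for (i in 1:14) for (j in 1:11) {
      bf <- min(sqrt((xs[j] - xs[tgt[, 2]])^2 + (ys[i] - ys[tgt[, 1]])^2))
      expect_equal(d$values[i, j], bf, tolerance = 1e-9)
    }
  }
})

test_that("normalize01 maps min to 0 and max to 1 exactly, keeping order", {
  r <- mk_num_raster(matrix(c(0, 5, 10, 5), 2))
  n <- normalize01(r)
  expect_equal(sort(unique(as.vector(n$values))), c(0, 0.5, 1))
  expect_equal(min(n$values), 0)
  expect_equal(max(n$values), 1)

  # already-[0,1] raster attaining both bounds is unchanged
  r01 <- mk_num_raster(matrix(c(0, 0.25, 1, 0.5), 2))
  expect_equal(normalize01(r01)$values, r01$values)

  set.seed(4)
  rr <- mk_num_raster(matrix(rnorm(100), 10))
  nn <- normalize01(rr)
  expect_true(all(nn$values >= 0 & nn$values <= 1))
  expect_equal(cor(as.vector(rr$values), as.vector(nn$values),
                   method = "spearman"), 1)

  expect_error(normalize01(mk_num_raster(matrix(3, 4, 4))), "constant")
})

# a small random landscape with roads and water present
random_landscape <- function(seed, nr = 30, nc = 30) {
  set.seed(seed)
  v <- matrix(sample(c(1L, 8L, 9L, 10L, 13L), nr * nc, replace = TRUE,
                     prob = c(0.3, 0.25, 0.15, 0.1, 0.2)), nr, nc)
  v[15, ] <- 16L     # a primary road
  v[1, 1] <- 12L     # a pond
  mk_raster(v, cell = 30)
}

test_that("the index is monotone: more buildings up, more forest down", {
  cfg <- index_config()
  for (seed in 1:10) {
    lulc <- random_landscape(seed)
    idx0 <- urbanization_index(lulc, cfg)
    # flip a forest-or-other block to buildings: index must not decrease
    v_up <- lulc$values
    v_up[5:10, 5:10] <- 13L
    idx_up <- urbanization_index(mk_raster(v_up), cfg)
    expect_true(all(idx_up$values[5:10, 5:10] - idx0$values[5:10, 5:10]
                    >= -1e-9))
    # flip the same block to forest: index must not increase
    v_dn <- lulc$values
    v_dn[5:10, 5:10] <- 8L
    idx_dn <- urbanization_index(mk_raster(v_dn), cfg)
    expect_true(all(idx_dn$values[5:10, 5:10] - idx0$values[5:10, 5:10]
                    <= 1e-9))
  }
})

test_that("index values respect the theoretical bounds of the weights", {
  cfg <- index_config()
  b <- index_bounds(cfg)
  expect_equal(b, c(0, 100), tolerance = 1e-9)
  for (seed in 1:5) {
    idx <- urbanization_index(random_landscape(seed), cfg)
    expect_true(all(idx$values >= b[1] - 1e-9 & idx$values <= b[2] + 1e-9))
  }
  # identity scale keeps the raw weighted-sum range
  cfg_id <- index_config(output_scale = "identity")
  bid <- index_bounds(cfg_id)
  expect_equal(bid, c(-1.25, 1.5))
})

test_that("index is translation-invariant and affine-equivariant", {
  lulc <- random_landscape(3)
  cfg <- index_config()
  idx <- urbanization_index(lulc, cfg)
  # translate the grid origin: values identical
  shifted <- cat_raster(lulc$values, lulc$xmin + 12345, lulc$ymax + 54321,
                        lulc$cell, lulc$crs, nodata = lulc$nodata)
  idx_s <- urbanization_index(shifted, cfg)
  expect_equal(idx_s$values, idx$values, tolerance = 1e-12)
  # output_scale affine equivariance
  cfg2 <- index_config(output_scale = list(offset = 7, factor = 2))
  cfg1 <- index_config(output_scale = "identity")
  i2 <- urbanization_index(lulc, cfg2)
  i1 <- urbanization_index(lulc, cfg1)
  expect_equal(i2$values, 7 + 2 * i1$values, tolerance = 1e-12)
})

test_that("extreme landscapes land at the extreme ends of the index", {
  cfg <- index_config()
  # all forest, roads at one far corner: near the grid minimum
  v_f <- matrix(8L, 20, 20); v_f[1, 1] <- 16L; v_f[1, 2] <- 12L
  idx_f <- urbanization_index(mk_raster(v_f), cfg)
  # all buildings adjacent to a road grid: near the maximum
  v_b <- matrix(13L, 20, 20); v_b[10, ] <- 16L; v_b[1, 1] <- 12L
  idx_b <- urbanization_index(mk_raster(v_b), cfg)
  expect_gt(min(idx_b$values), max(idx_f$values[-c(1, 21, 41)]))
})

test_that("landscapes without water still index, with a warning", {
  v <- matrix(13L, 10, 10); v[5, ] <- 16L
  expect_warning(idx <- urbanization_index(mk_raster(v), index_config()),
                 "water")
  expect_true(all(is.finite(idx$values)))
})
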