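#' Urbanization-index configuration
#'
#' Holds every tunable of the index: focal window sides for the vegetation
#' and building proportions, the 3:2:1 shelter weights for forest, low
#' vegetation and open green, the signed weights of the four combined
#' components, the code sets defining major roads and water, and the final
#' affine output scaling. All components lie in `[0, 1]` before weighting:
#' the shelter-weighted vegetation proportion, the building proportion, road
#' proximity `1 - d_road` and water proximity `1 - d_water` (distances min-max
#' normalized to `[0, 1]`). Defaults make the index increase with urban
#' intensity: buildings and road proximity push it up, vegetation and water
#' proximity pull it down. By default the theoretical range implied by the
#' weights is mapped to `[0, 100]`.
#'
#' @param veg_window focal window side for vegetation proportions (m).
#' @param bld_window focal window side for the building proportion (m).
#' @param veg_weights named weights for `forest`, `low_veg`, `open_green`.
#' @param component_weights signed weights for `vegetation`, `building`,
#'   `road`, `water`.
#' @param forest_codes,low_veg_codes,open_green_codes,building_codes,major_road_codes,water_codes
#'   framework class codes feeding each component.
#' @param output_scale `list(offset =, factor =)` applied last
#'   (`scaled = offset + factor * raw`), or `NULL` to derive the default
#'   `[0, 100]` mapping from the component weights, or `"identity"`.
#' @return An object of class `index_config`.
#' @export
index_config <- function(veg_window = 900, bld_window = 450,
                         veg_weights = c(forest = 3, low_veg = 2,
                                         open_green = 1),
                         component_weights = c(vegetation = -1, building = 1,
                                               road = 0.5, water = -0.25),
                         forest_codes = 8L, low_veg_codes = 9L,
                         open_green_codes = 10L, building_codes = 13L,
                         major_road_codes = c(15L, 16L, 18L, 23L),
                         water_codes = 12L,
                         output_scale = NULL) {
  if (veg_window <= 0 || bld_window <= 0) um_stop("windows must be positive")
  need <- c("vegetation", "building", "road", "water")
  if (!all(need %in% names(component_weights))) {
    um_stop("component_weights needs entries: ", paste(need, collapse = ", "))
  }
  if (identical(output_scale, "identity")) {
    output_scale <- list(offset = 0, factor = 1)
  }
  if (is.null(output_scale)) {
    w <- component_weights[need]
    lo <- sum(pmin(w, 0))
    hi <- sum(pmax(w, 0))
    output_scale <- list(offset = -lo * 100 / (hi - lo),
                         factor = 100 / (hi - lo))
  }
  structure(list(
    veg_window = veg_window, bld_window = bld_window,
    veg_weights = veg_weights, component_weights = component_weights,
    forest_codes = forest_codes, low_veg_codes = low_veg_codes,
    open_green_codes = open_green_codes, building_codes = building_codes,
    major_road_codes = major_road_codes, water_codes = water_codes,
    output_scale = output_scale
  ), class = "index_config")
}

#' Theoretical index bounds implied by a configuration
#'
#' Every component lies in `[0, 1]`, so the raw index is bounded by the sums
#' of the negative and positive component weights; the bounds are then pushed
#' through the output scaling.
#'
#' @param cfg an [index_config()].
#' @return Numeric `c(min, max)` on the output scale.
#' @export
index_bounds <- function(cfg) {
  w <- cfg$component_weights[c("vegetation", "building", "road", "water")]
  raw <- c(sum(pmin(w, 0)), sum(pmax(w, 0)))
  sort(cfg$output_scale$offset + cfg$output_scale$factor * raw)
}

#' Focal proportion by block aggregation
#'
#' Aggregates a binary class mask into `window / cell` blocks (the fraction
#' of coded cells per block) and disaggregates the block values back to the
#' working grid, so each cell carries the coded-surface proportion of its
#' surrounding block. Edge blocks use the cells actually present.
#'
#' @param mask a binary [cat_raster()] (`code` vs nodata).
#' @param window block side length in meters; must be a multiple of the cell
#'   size.
#' @return A [num_raster()] with values in `[0, 1]`.
#' @export
focal_proportion <- function(mask, window) {
  stopifnot(inherits(mask, "cat_raster"))
  f <- window / mask$cell
  if (f < 1 || abs(f - round(f)) > 1e-9) {
    um_stop("window (", window, " m) must be a positive multiple of the ",
            "cell size (", mask$cell, " m)")
  }
  f <- as.integer(round(f))
  v <- 1 * (mask$values != mask$nodata)
  nr <- nrow(v); nc <- ncol(v)
  bi <- (seq_len(nr) - 1L) %/% f + 1L
  bj <- (seq_len(nc) - 1L) %/% f + 1L
  counts <- rowsum(v, bi, reorder = TRUE)
  counts <- t(rowsum(t(counts), bj, reorder = TRUE))
  ones <- matrix(1, nr, nc)
  tot <- rowsum(ones, bi, reorder = TRUE)
  tot <- t(rowsum(t(tot), bj, reorder = TRUE))
  prop <- counts / tot
  out <- prop[bi, bj, drop = FALSE]
  num_raster(out, mask$xmin, mask$ymax, mask$cell, mask$crs)
}

# Exact 1-D squared Euclidean distance transform (lower envelope of
# parabolas), distances in cell units. Off-site cells must carry a large
# finite value (not Inf: the parabola intersection would be NaN).
edt_1d <- function(f) {
  n <- length(f)
  if (n == 1) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  isec <- function(q, p) ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
  for (q in 2:n) {
    s <- isec(q, v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- isec(q, v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Euclidean distance to the nearest target cell
#'
#' Exact Euclidean distance (meters) from every cell center to the nearest
#' center of a cell carrying one of the target codes, via the separable
#' squared-distance transform; target cells get 0.
#'
#' @param r a [cat_raster()].
#' @param targets class codes defining the target set.
#' @return A [num_raster()] of distances in meters.
#' @export
distance_to <- function(r, targets) {
  stopifnot(inherits(r, "cat_raster"))
  on <- r$values %in% targets
  if (!any(on)) {
    um_stop("no cells carry any target code (",
            paste(targets, collapse = ", "), ")")
  }
  f <- matrix(1e12, nrow(r$values), ncol(r$values))  # large finite off-site
  f[on] <- 0
  # columns then rows (separable)
  for (j in seq_len(ncol(f))) f[, j] <- edt_1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- edt_1d(f[i, ])
  num_raster(sqrt(f) * r$cell, r$xmin, r$ymax, r$cell, r$crs)
}

#' Min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)`; the minimum cell maps to exactly 0 and the
#' maximum cell to exactly 1. A constant raster has no defined normalization
#' and errors.
#'
#' @param r a [num_raster()].
#' @return A [num_raster()] in `[0, 1]`.
#' @export
normalize01 <- function(r) {
  stopifnot(inherits(r, "num_raster"))
  lo <- min(r$values, na.rm = TRUE)
  hi <- max(r$values, na.rm = TRUE)
  if (hi <= lo) um_stop("constant raster: min-max normalization is undefined")
  num_raster((r$values - lo) / (hi - lo), r$xmin, r$ymax, r$cell, r$crs)
}

mask_of <- function(lulc, codes) {
  v <- matrix(0L, nrow(lulc$values), ncol(lulc$values))
  v[lulc$values %in% codes] <- 1L
  cat_raster(v, lulc$xmin, lulc$ymax, lulc$cell, lulc$crs, nodata = 0L)
}

#' OSM-derived urbanization index
#'
#' Combines, as an arithmetic weighted sum on the working 30 m grid:
#' the shelter-weighted focal vegetation proportion
#' `(3 P_forest + 2 P_lowveg + 1 P_open) / 6` (900 m window), the focal
#' building proportion (450 m window), proximity to major roads and railways
#' (`1 -` min-max-normalized distance) and proximity to water. Under the
#' default signed weights the index is strictly increasing in the building
#' proportion and road proximity and strictly decreasing in every vegetation
#' proportion and water proximity, and is finally mapped to the output scale
#' (default `[0, 100]`). Landscapes with no road or water cells get a zero
#' contribution from that component, with a warning.
#'
#' @param lulc a framework-legend [cat_raster()].
#' @param cfg an [index_config()].
#' @return A [num_raster()] of index values.
#' @export
urbanization_index <- function(lulc, cfg = index_config()) {
  stopifnot(inherits(lulc, "cat_raster"), inherits(cfg, "index_config"))
  vw <- cfg$veg_weights
  p_forest <- focal_proportion(mask_of(lulc, cfg$forest_codes), cfg$veg_window)
  p_lowveg <- focal_proportion(mask_of(lulc, cfg$low_veg_codes),
                               cfg$veg_window)
  p_open <- focal_proportion(mask_of(lulc, cfg$open_green_codes),
                             cfg$veg_window)
  veg <- (vw[["forest"]] * p_forest$values +
          vw[["low_veg"]] * p_lowveg$values +
          vw[["open_green"]] * p_open$values) / sum(vw)
  bld <- focal_proportion(mask_of(lulc, cfg$building_codes),
                          cfg$bld_window)$values
  prox <- function(codes, label) {
    if (!any(lulc$values %in% codes)) {
      um_warn("no ", label, " cells in the landscape; its proximity ",
              "component contributes 0")
      return(matrix(0, nrow(lulc$values), ncol(lulc$values)))
    }
    d <- distance_to(lulc, codes)
    if (max(d$values) <= min(d$values)) {
      return(matrix(1, nrow(lulc$values), ncol(lulc$values)))
    }
    1 - normalize01(d)$values
  }
  road <- prox(cfg$major_road_codes, "major-road/railway")
  water <- prox(cfg$water_codes, "water")
  w <- cfg$component_weights
  raw <- w[["vegetation"]] * veg + w[["building"]] * bld +
    w[["road"]] * road + w[["water"]] * water
  out <- cfg$output_scale$offset + cfg$output_scale$factor * raw
  num_raster(out, lulc$xmin, lulc$ymax, lulc$cell, lulc$crs)
}
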