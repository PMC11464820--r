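#' Recipe for a synthetic tagged-feature city
#'
#' Describes a deterministic (seeded) gridded city: a square extent cut into
#' blocks by a regular road lattice, blocks assigned to land-use and green
#' classes from a mosaic weight table, buildings dropped on slots inside
#' developed blocks, an optional water body, and one specimen feature per
#' registry rule so every classification rule is exercised. All shape edges
#' are laid on a 6 m lattice chosen so no 30 m cell center ever falls exactly
#' on a polygon edge, which keeps cell-center rasterization unambiguous.
#'
#' @param seed integer seed driving every random choice.
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in meters.
#' @param road_grid_spacing distance between road centerlines (m); must be a
#'   multiple of the 30 m cell and divide the extent sides.
#' @param lane_table named lane counts per road class name; must mirror the
#'   registry defaults so lane imputation is exact.
#' @param building_density probability a building slot is occupied.
#' @param park_fraction fraction of blocks assigned to green cover.
#' @param void_fraction fraction of blocks left unmapped (no feature at all;
#'   these become the planted nodata voids).
#' @param water optional `c(xmin, ymin, xmax, ymax)` water body.
#' @param crs projected CRS identifier.
#' @return An object of class `city_recipe`.
#' @export
city_recipe <- function(seed = 42L,
                        extent = c(0, 0, 6000, 6000),
                        road_grid_spacing = 600,
                        lane_table = c(motorway = 4, primary_road = 3,
                                       secondary_road = 2, tertiary_road = 2,
                                       residential_road = 2, service_road = 1,
                                       road_unknown = 2),
                        building_density = 0.3,
                        park_fraction = 0.2,
                        void_fraction = 0.08,
                        water = c(4800, 4800, 5400, 5760),
                        crs = "EPSG:32616") {
  extent <- check_bbox(extent)
  if (road_grid_spacing %% 30 != 0) {
    um_stop("road_grid_spacing must be a multiple of the 30 m cell")
  }
  if (building_density < 0 || building_density > 1 ||
      park_fraction < 0 || park_fraction > 1 ||
      void_fraction < 0 || void_fraction > 1) {
    um_stop("fractions must lie in [0, 1]")
  }
  max_width <- 6 * max(lane_table)
  if (road_grid_spacing <= 2 * max_width) {
    um_stop("road_grid_spacing must exceed twice the widest road width")
  }
  structure(list(seed = seed, extent = extent,
                 road_grid_spacing = road_grid_spacing,
                 lane_table = lane_table,
                 building_density = building_density,
                 park_fraction = park_fraction,
                 void_fraction = void_fraction,
                 water = water, crs = crs),
            class = "city_recipe")
}

# specimen land-use / green classes pinned to the first blocks so that every
# polygon rule fires at least once regardless of the mosaic draw
specimen_block_classes <- function() {
  c(residential = 1L, commercial = 2L, industrial = 3L, institutional = 4L,
    recreation = 5L, cemetery = 6L, protected_green = 7L, forest = 8L,
    low_vegetation = 9L, open_green = 10L, barren = 11L,
    construction_site = 25L, agriculture = 27L)
}

# a representative tag set per polygon class
polygon_class_tags <- function(code) {
  switch(as.character(code),
    "1" = c(landuse = "residential"),
    "2" = c(landuse = "commercial"),
    "3" = c(landuse = "industrial"),
    "4" = c(amenity = "school"),
    "5" = c(leisure = "pitch"),
    "6" = c(landuse = "cemetery"),
    "7" = c(boundary = "protected_area"),
    "8" = c(landuse = "forest"),
    "9" = c(landuse = "meadow"),
    "10" = c(leisure = "park"),
    "11" = c(natural = "sand"),
    "12" = c(natural = "water"),
    "13" = c(building = "yes"),
    "14" = c(amenity = "parking"),
    "25" = c(landuse = "construction"),
    "27" = c(landuse = "farmland"),
    um_stop("no tag template for polygon class ", code)
  )
}

line_class_tags <- function(code, lanes = NULL) {
  tags <- switch(as.character(code),
    "15" = c(highway = "motorway"),
    "16" = c(highway = "primary"),
    "17" = c(highway = "unclassified"),
    "18" = c(highway = "secondary"),
    "19" = c(highway = "tertiary"),
    "20" = c(highway = "residential"),
    "21" = c(highway = "service"),
    "22" = c(highway = "path"),
    "23" = c(railway = "rail"),
    "24" = c(barrier = "fence"),
    "26" = c(highway = "construction"),
    um_stop("no tag template for line class ", code)
  )
  if (!is.null(lanes)) tags <- c(tags, lanes = as.character(lanes))
  tags
}

line_class_names <- c("15" = "motorway", "16" = "primary_road",
                      "17" = "road_unknown", "18" = "secondary_road",
                      "19" = "tertiary_road", "20" = "residential_road",
                      "21" = "service_road", "22" = "hiking_path",
                      "23" = "railway", "24" = "fence",
                      "26" = "construction_linear")

# fixed buffer widths of the non-road line classes (mirrors the registry)
fixed_width_table <- c("22" = 2, "23" = 6, "24" = 1, "26" = 12)

#' Generate a synthetic city and its analytically known class raster
#'
#' Emits a tagged feature collection (roads with sometimes-missing or
#' unparseable `lanes` tags, buildings, parking, land-use and green blocks,
#' water, specimen lines for every linear class, one untaggable feature for
#' the unclassified bin) together with the ground-truth 30 m class raster.
#' The ground truth is computed by direct interval arithmetic on the placed
#' axis-aligned shapes — a code path disjoint from the classification /
#' buffering / ray-casting pipeline, sharing only the placement table, the
#' lane-width constants and the priority ranks — so pipeline agreement with
#' it is evidence of correctness, not a tautology.
#'
#' @param recipe a [city_recipe()].
#' @param reg the [class_registry()] the ground truth should honor.
#' @return List with `features` ([tagged_features()]), `ground_truth` (the
#'   [cat_raster()] the pipeline should reproduce, nodata in void blocks),
#'   `reference` (full-coverage truth including the withheld void-block
#'   classes, for accuracy assessment), `shapes` / `hidden_shapes`
#'   (placement tables), `grid` ([grid_spec()]), `recipe`.
#' @export
generate_city <- function(recipe = city_recipe(), reg = default_registry()) {
  stopifnot(inherits(recipe, "city_recipe"))
  set.seed(recipe$seed)
  ext <- recipe$extent
  sp <- recipe$road_grid_spacing
  grid <- grid_spec(ext, 30, recipe$crs)
  feats <- list()
  shapes <- list()  # placement table: rects with class code + rank
  nid <- 0L
  new_id <- function(prefix) {
    nid <<- nid + 1L
    paste0(prefix, nid)
  }
  add_feat <- function(prefix, geometry, tags) {
    feats[[length(feats) + 1L]] <<- tagged_feature(new_id(prefix), geometry,
                                                   tags)
  }
  add_rect_shape <- function(code, xmin, ymin, xmax, ymax) {
    shapes[[length(shapes) + 1L]] <<- list(
      code = as.integer(code), xmin = xmin, ymin = ymin,
      xmax = xmax, ymax = ymax)
  }

  # --- road lattice ---------------------------------------------------------
  # centerlines sit on the cell-center lattice (15 mod 30 m) so every road,
  # however narrow, paints a one-cell strip; buffer edges at center +/- 3k
  # (k = lanes, k <= 4) never coincide with a cell center
  xs <- seq(ext["xmin"] + sp, ext["xmax"] - sp, by = sp) + 15
  ys <- seq(ext["ymin"] + sp, ext["ymax"] - sp, by = sp) + 15
  road_cycle <- c("secondary_road", "residential_road", "tertiary_road",
                  "residential_road", "primary_road", "residential_road",
                  "tertiary_road", "residential_road", "secondary_road")
  road_class_code <- c(motorway = 15L, primary_road = 16L,
                       road_unknown = 17L, secondary_road = 18L,
                       tertiary_road = 19L, residential_road = 20L,
                       service_road = 21L)
  emit_road <- function(vertical, coord, k) {
    type <- road_cycle[(k - 1L) %% length(road_cycle) + 1L]
    # one horizontal mid-lattice road is promoted to a motorway so the
    # major-road distance layer always has a motorway
    if (!vertical && k == ceiling(length(ys) / 2)) type <- "motorway"
    code <- road_class_code[[type]]
    default_lanes <- recipe$lane_table[[type]]
    u <- stats::runif(1)
    if (u < 0.4) {            # explicit, sometimes non-default, lanes tag
      lanes_true <- max(1, min(4, default_lanes + sample(c(-1L, 0L, 1L), 1)))
      lanes_tag <- as.character(lanes_true)
    } else if (u < 0.5) {     # unparseable tag: falls back to the default
      lanes_true <- default_lanes
      lanes_tag <- "two"
    } else {                  # missing tag: imputed from the type mean
      lanes_true <- default_lanes
      lanes_tag <- NULL
    }
    width <- 6 * lanes_true
    if (vertical) {
      g <- geom_line(rbind(c(coord, ext["ymin"]), c(coord, ext["ymax"])))
      add_rect_shape(code, coord - width / 2, ext[["ymin"]],
                     coord + width / 2, ext[["ymax"]])
    } else {
      g <- geom_line(rbind(c(ext["xmin"], coord), c(ext["xmax"], coord)))
      add_rect_shape(code, ext[["xmin"]], coord - width / 2,
                     ext[["xmax"]], coord + width / 2)
    }
    add_feat("road", g, line_class_tags(code, lanes = lanes_tag))
  }
  for (k in seq_along(xs)) emit_road(TRUE, xs[k], k)
  for (k in seq_along(ys)) emit_road(FALSE, ys[k], k)

  # --- land-use / green mosaic over blocks ---------------------------------
  bx <- seq(ext["xmin"], ext["xmax"] - sp, by = sp)
  by <- seq(ext["ymin"], ext["ymax"] - sp, by = sp)
  blocks <- expand.grid(x0 = bx, y0 = by)
  nb <- nrow(blocks)
  spec_cls <- specimen_block_classes()
  block_class <- integer(nb)
  block_class[seq_along(spec_cls)] <- spec_cls
  green <- c("8" = 0.4, "10" = 0.35, "9" = 0.25)  # forest/open/low split
  rest <- max(0, 1 - recipe$park_fraction - recipe$void_fraction)
  w_urban <- c("1" = 0.55, "2" = 0.15, "3" = 0.10, "4" = 0.06, "5" = 0.04,
               "6" = 0.02, "25" = 0.03, "27" = 0.05)
  pool <- c(as.numeric(green) * recipe$park_fraction,
            rep(recipe$void_fraction, 1),
            as.numeric(w_urban) * rest)
  pool_codes <- c(as.integer(names(green)), NA_integer_,
                  as.integer(names(w_urban)))
  draw <- sample(seq_along(pool), nb - length(spec_cls), replace = TRUE,
                 prob = pool)
  block_class[(length(spec_cls) + 1L):nb] <- pool_codes[draw]
  # void blocks still have a true class (drawn here, withheld from the
  # features) so a full-coverage reference raster exists for accuracy work
  hidden <- list()
  for (b in seq_len(nb)) {
    cls <- block_class[b]
    x0 <- blocks$x0[b]; y0 <- blocks$y0[b]
    if (is.na(cls)) {  # planted void: class known, feature withheld
      hcls <- sample(c(8L, 9L, 27L), 1, prob = c(0.4, 0.35, 0.25))
      hidden[[length(hidden) + 1L]] <- list(
        code = hcls, xmin = x0, ymin = y0, xmax = x0 + sp, ymax = y0 + sp)
      next
    }
    add_feat("block", geom_rect(x0, y0, x0 + sp, y0 + sp),
             polygon_class_tags(cls))
    add_rect_shape(cls, x0, y0, x0 + sp, y0 + sp)
  }

  # --- buildings and parking on slots inside developed blocks ---------------
  slot_off <- c(60, 180, 300, 420)
  bsize <- 60
  for (b in seq_len(nb)) {
    cls <- block_class[b]
    if (is.na(cls) || !cls %in% c(1L, 2L, 3L, 4L)) next
    x0 <- blocks$x0[b]; y0 <- blocks$y0[b]
    # specimen residential block always builds slot 1; specimen commercial
    # block always fills slot 1 (which it converts to parking)
    guaranteed <- b %in% c(1L, 2L)
    si <- 0L
    for (ox in slot_off) for (oy in slot_off) {
      si <- si + 1L
      take <- stats::runif(1) < recipe$building_density ||
        (guaranteed && si == 1L)
      if (!take || recipe$building_density == 0) next
      # the specimen commercial block turns its first slot into parking
      code <- if (cls == 2L && b == 2L && si == 1L) 14L else 13L
      add_feat(if (code == 13L) "bld" else "park",
               geom_rect(x0 + ox, y0 + oy, x0 + ox + bsize, y0 + oy + bsize),
               polygon_class_tags(code))
      add_rect_shape(code, x0 + ox, y0 + oy, x0 + ox + bsize, y0 + oy + bsize)
    }
  }

  # --- water body -----------------------------------------------------------
  if (!is.null(recipe$water)) {
    w <- check_bbox(recipe$water)
    add_feat("water", geom_rect(w["xmin"], w["ymin"], w["xmax"], w["ymax"]),
             polygon_class_tags(12L))
    add_rect_shape(12L, w[["xmin"]], w[["ymin"]], w[["xmax"]], w[["ymax"]])
  }

  # --- specimen lines: one per linear class not in the lattice --------------
  # y positions chosen so buffered edges avoid cell centers (centers sit at
  # 15 mod 30 m) while each buffer still strictly contains one center row
  specimen_lines <- list(
    list(code = 17L, y = 132),   # half-width 6   -> edges 126/138, covers 135
    list(code = 21L, y = 165),   # half-width 3   -> edges 162/168, covers 165
    list(code = 22L, y = 195),   # half-width 1   -> edges 194/196, covers 195
    list(code = 24L, y = 225),   # half-width 0.5 -> edges 224.5/225.5
    list(code = 23L, y = 255),   # half-width 3   -> edges 252/258, covers 255
    list(code = 26L, y = 282)    # half-width 6   -> edges 276/288, covers 285
  )
  for (sl in specimen_lines) {
    x_from <- ext[["xmin"]] + 60
    x_to <- ext[["xmax"]] - 60
    g <- geom_line(rbind(c(x_from, sl$y), c(x_to, sl$y)))
    add_feat("line", g, line_class_tags(sl$code))
    cname <- line_class_names[[as.character(sl$code)]]
    width <- if (as.character(sl$code) %in% names(fixed_width_table)) {
      fixed_width_table[[as.character(sl$code)]]
    } else 6 * recipe$lane_table[[cname]]
    add_rect_shape(sl$code, x_from, sl$y - width / 2, x_to, sl$y + width / 2)
  }

  # one feature no rule can classify (diagnostics bin)
  add_feat("odd", geom_rect(66, 66, 126, 126), c(note = "unmapped land"))

  fc <- tagged_features(feats, recipe$crs)

  # --- ground truth by interval arithmetic ----------------------------------
  cx <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell
  cy <- grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$cell
  gt <- matrix(0L, grid$nrow, grid$ncol)
  ranks <- reg$priority
  shape_rank <- vapply(shapes, function(s) ranks[[as.character(s$code)]], 0L)
  for (s in shapes[order(shape_rank)]) {
    cols <- which(cx > s$xmin & cx < s$xmax)
    rows <- which(cy > s$ymin & cy < s$ymax)
    if (length(cols) && length(rows)) gt[rows, cols] <- s$code
  }
  ground_truth <- cat_raster(gt, grid$xmin, grid$ymax, grid$cell, grid$crs,
                             nodata = 0L)
  # reference raster: ground truth plus the withheld void-block classes
  # (hidden blocks rank below everything mapped, so fill only empty cells)
  ref <- gt
  for (s in hidden) {
    cols <- which(cx > s$xmin & cx < s$xmax)
    rows <- which(cy > s$ymin & cy < s$ymax)
    if (length(cols) && length(rows)) {
      sub <- ref[rows, cols, drop = FALSE]
      sub[sub == 0L] <- s$code
      ref[rows, cols] <- sub
    }
  }
  reference <- cat_raster(ref, grid$xmin, grid$ymax, grid$cell, grid$crs,
                          nodata = 0L)
  list(features = fc, ground_truth = ground_truth, reference = reference,
       shapes = shapes, hidden_shapes = hidden, grid = grid, recipe = recipe)
}

#' Run the classify-buffer-rasterize-merge pipeline on a feature collection
#'
#' Convenience wrapper producing the merged detail raster from raw tagged
#' features: classify, buffer every line class, rasterize each class mask,
#' merge under the priority table.
#'
#' @param fc a [tagged_features()] collection.
#' @param grid a [grid_spec()].
#' @param reg a [class_registry()].
#' @return A [cat_raster()].
#' @export
build_lulc <- function(fc, grid, reg = default_registry()) {
  layers <- classify_features(fc, reg)
  layers$unclassified <- NULL
  masks <- list()
  for (code in names(layers)) {
    rule <- registry_rule(reg, as.integer(code))
    cl <- layers[[code]]
    if (rule$geometry_kind == "line") cl <- buffer_lines(cl, reg)
    masks[[code]] <- rasterize_class(cl, grid, as.integer(code))
  }
  merge_layers(masks, reg)
}

#' Generate a synthetic global land-cover raster
#'
#' A blobby multi-class categorical raster emulating a coarse global product:
#' a "built" class concentrated around the extent center (hitting a requested
#' areal fraction exactly, up to ties) and smooth patches of forest,
#' grassland, cropland, water and barren elsewhere. The legend exercises
#' every path of the default reclassification, including built to
#' developed-unknown.
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)`.
#' @param cell_size cell size in meters.
#' @param seed integer seed.
#' @param built_fraction target areal fraction of the built class.
#' @param crs projected CRS identifier.
#' @return A [cat_raster()] with global legend codes
#'   (1 forest, 2 grassland, 3 cropland, 5 water, 6 barren, 17 built).
#' @export
generate_global_lulc <- function(extent, cell_size = 30, seed = 1L,
                                 built_fraction = 0.3, crs = "EPSG:32616") {
  grid <- grid_spec(check_bbox(extent), cell_size, crs)
  set.seed(seed)
  smooth_field <- function(nr, nc, passes = 3L, k = 9L) {
    f <- matrix(stats::runif(nr * nc), nr, nc)
    for (p in seq_len(passes)) {
      f <- t(apply(f, 1, function(v) {
        stats::filter(v, rep(1 / k, k), circular = TRUE)
      }))
      f <- apply(f, 2, function(v) {
        stats::filter(v, rep(1 / k, k), circular = TRUE)
      })
    }
    f
  }
  nr <- grid$nrow; nc <- grid$ncol
  rowc <- (seq_len(nr) - (nr + 1) / 2) / nr
  colc <- (seq_len(nc) - (nc + 1) / 2) / nc
  radial <- sqrt(outer(rowc^2, colc^2, "+"))
  core <- smooth_field(nr, nc) * 0.25 - radial  # urban core: high near center
  v <- matrix(0L, nr, nc)
  if (built_fraction > 0) {
    thr <- stats::quantile(core, 1 - built_fraction, names = FALSE)
    v[core > thr] <- 17L
    n_built <- round(built_fraction * nr * nc)
    short <- n_built - sum(v == 17L)
    if (short > 0) {  # resolve ties at the threshold deterministically
      at <- which(core == thr)
      v[at[seq_len(min(short, length(at)))]] <- 17L
    }
  }
  nat <- smooth_field(nr, nc)
  open <- v == 0L
  qs <- stats::quantile(nat[open], c(0.30, 0.55, 0.75, 0.90), names = FALSE)
  v[open & nat <= qs[1]] <- 1L                  # forest
  v[open & nat > qs[1] & nat <= qs[2]] <- 2L    # grassland
  v[open & nat > qs[2] & nat <= qs[3]] <- 3L    # cropland
  v[open & nat > qs[3] & nat <= qs[4]] <- 5L    # water
  v[open & nat > qs[4]] <- 6L                   # barren
  legend <- c("1" = "forest", "2" = "grassland", "3" = "cropland",
              "5" = "water", "6" = "barren", "17" = "built")
  cat_raster(v, grid$xmin, grid$ymax, grid$cell, grid$crs,
             nodata = 0L, legend = legend)
}

#' Default reclassification of the synthetic global legend
#'
#' @return List with `entries` (named global code -> framework code) and
#'   `developed_codes` (global codes sent to class 28).
#' @export
default_reclass_map <- function() {
  list(entries = c("1" = 8L, "2" = 9L, "3" = 27L, "5" = 12L, "6" = 11L),
       developed_codes = 17L)
}

#' Recipe for simulated detection histories
#'
#' @param seed integer seed.
#' @param n_sites number of camera sites (>= 2).
#' @param n_seasons number of primary sampling seasons.
#' @param weeks_per_season weeks sampled per season (scalar or per-season
#'   vector); weeks beyond a season's count are missing.
#' @param beta occupancy coefficients `c(intercept, slope)` (slope used when
#'   covariate values are supplied or drawn).
#' @param theta autologistic carry-over.
#' @param alpha detection intercept (logit weekly detection probability).
#' @param x site covariate values; `NULL` draws standard-normal values.
#' @return An object of class `occ_sim_recipe`.
#' @export
occ_sim_recipe <- function(seed = 1L, n_sites = 100L, n_seasons = 4L,
                           weeks_per_season = 6L,
                           beta = c(-0.5, 0.8), theta = 1, alpha = 0.5,
                           x = NULL) {
  if (n_sites < 2) um_stop("n_sites must be >= 2")
  if (n_seasons < 1) um_stop("n_seasons must be >= 1")
  structure(list(seed = seed, n_sites = as.integer(n_sites),
                 n_seasons = as.integer(n_seasons),
                 weeks_per_season = weeks_per_season,
                 beta = beta, theta = theta, alpha = alpha, x = x),
            class = "occ_sim_recipe")
}

#' Simulate detection histories from the autologistic occupancy model
#'
#' Draws `z_1 ~ Bernoulli(invlogit(x' beta))`,
#' `z_t ~ Bernoulli(invlogit(x' beta + theta z_{t-1}))` and weekly detections
#' `y ~ Bernoulli(p z_t)` with `p = invlogit(alpha)`; deterministic under the
#' recipe seed.
#'
#' @param recipe an [occ_sim_recipe()].
#' @return List with `history` ([detection_history()]), `cov`
#'   (`site_covariates` on the simulated values, unstandardized), `z` (latent
#'   states), `recipe`.
#' @export
simulate_detections <- function(recipe = occ_sim_recipe()) {
  stopifnot(inherits(recipe, "occ_sim_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n_sites
  T_ <- recipe$n_seasons
  wk <- rep(recipe$weeks_per_season, length.out = T_)
  x <- recipe$x %||% stats::rnorm(n)
  eta <- recipe$beta[1] + (if (length(recipe$beta) > 1)
    recipe$beta[2] * x else 0)
  p <- invlogit(recipe$alpha)
  z <- matrix(0L, n, T_)
  z[, 1] <- stats::rbinom(n, 1, invlogit(eta))
  if (T_ > 1) {
    for (t in 2:T_) {
      z[, t] <- stats::rbinom(n, 1, invlogit(eta + recipe$theta * z[, t - 1]))
    }
  }
  y <- array(NA_integer_, c(n, T_, max(wk)))
  for (t in seq_len(T_)) {
    for (w in seq_len(wk[t])) {
      y[, t, w] <- stats::rbinom(n, 1, p * z[, t])
    }
  }
  list(history = detection_history(y),
       cov = site_covariates(x, standardize = FALSE),
       z = z, recipe = recipe)
}
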