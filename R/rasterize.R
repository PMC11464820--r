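#' Working grid specification
#'
#' Snaps a bounding box outward so both sides are positive multiples of the
#' cell size, keeping the requested lower-left corner fixed.
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)`.
#' @param cell_size cell size in meters (default 30, the resolution at which
#'   the framework integrates with global land-cover products).
#' @param crs projected CRS identifier.
#' @return An object of class `grid_spec` with fields `xmin`, `ymin`, `xmax`,
#'   `ymax`, `cell`, `nrow`, `ncol`, `crs`.
#' @export
grid_spec <- function(bbox, cell_size = 30, crs) {
  bbox <- check_bbox(bbox)
  if (cell_size <= 0) um_stop("cell_size must be > 0")
  check_projected_crs(crs)
  ncol <- ceiling((bbox["xmax"] - bbox["xmin"]) / cell_size - 1e-9)
  nrow <- ceiling((bbox["ymax"] - bbox["ymin"]) / cell_size - 1e-9)
  structure(list(
    xmin = bbox[["xmin"]], ymin = bbox[["ymin"]],
    xmax = bbox[["xmin"]] + unname(ncol) * cell_size,
    ymax = bbox[["ymin"]] + unname(nrow) * cell_size,
    cell = cell_size, nrow = as.integer(nrow), ncol = as.integer(ncol),
    crs = crs
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$nrow, "x", x$ncol, " cells @ ", x$cell, " m, crs ",
      x$crs, "\n", sep = "")
  invisible(x)
}

empty_raster <- function(grid, nodata = 0L, legend = NULL) {
  cat_raster(matrix(nodata, grid$nrow, grid$ncol),
             xmin = grid$xmin, ymax = grid$ymax, cell = grid$cell,
             crs = grid$crs, nodata = nodata, legend = legend)
}

#' Rasterize one class layer
#'
#' A cell takes `code` iff its center point lies inside any polygon of the
#' collection (cell-center containment, the convention of the common raster
#' engines); all other cells take the nodata code.
#'
#' @param fc a [tagged_features()] collection of polygons (lines must be
#'   buffered first).
#' @param grid a [grid_spec()].
#' @param code integer class code to burn in.
#' @return A binary-mask [cat_raster()] coded `{code, nodata}`.
#' @export
rasterize_class <- function(fc, grid, code) {
  stopifnot(inherits(fc, "tagged_features"), inherits(grid, "grid_spec"))
  if (!identical(fc$crs, grid$crs)) {
    um_stop("feature CRS (", fc$crs, ") does not match grid CRS (",
            grid$crs, ")")
  }
  vals <- matrix(0L, grid$nrow, grid$ncol)
  xs <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell
  ys <- grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$cell
  for (f in fc$features) {
    g <- f$geometry
    if (g$type != "polygon") {
      um_stop("rasterize_class expects polygons; feature ", f$id,
              " is a line (buffer it first)")
    }
    bb <- geom_bbox(g)
    cols <- which(xs >= bb["xmin"] & xs <= bb["xmax"])
    rows <- which(ys >= bb["ymin"] & ys <= bb["ymax"])
    if (!length(cols) || !length(rows)) next
    px <- rep(xs[cols], times = length(rows))
    py <- rep(ys[rows], each = length(cols))
    inside <- points_in_polygon(px, py, g)
    if (any(inside)) {
      idx <- cbind(rep(rows, each = length(cols))[inside],
                   rep(cols, times = length(rows))[inside])
      vals[idx] <- as.integer(code)
    }
  }
  cat_raster(vals, grid$xmin, grid$ymax, grid$cell, grid$crs, nodata = 0L)
}

#' Merge per-class masks under the priority table
#'
#' Each output cell takes the code of the highest-priority mask coding it;
#' cells coded by no mask stay nodata. Raising a class's rank can only gain
#' it cells, never lose them.
#'
#' @param masks named list (names = class codes) of binary [cat_raster()]
#'   masks on one shared grid.
#' @param reg a [class_registry()] supplying priority ranks.
#' @return A [cat_raster()] with the merged classification.
#' @export
merge_layers <- function(masks, reg) {
  stopifnot(inherits(reg, "class_registry"))
  if (!length(masks)) um_stop("no masks to merge")
  codes <- as.integer(names(masks))
  if (any(is.na(codes))) um_stop("masks must be named by class code")
  miss <- setdiff(codes, as.integer(names(reg$priority)))
  if (length(miss)) {
    um_stop("no priority rank for class(es): ", paste(miss, collapse = ", "))
  }
  ref <- masks[[1]]
  for (m in masks) check_same_grid(ref, m, "masks")
  ranks <- reg$priority[as.character(codes)]
  out <- matrix(0L, nrow(ref$values), ncol(ref$values))
  for (i in order(ranks)) {
    m <- masks[[i]]
    coded <- m$values != m$nodata
    out[coded] <- codes[i]
  }
  cat_raster(out, ref$xmin, ref$ymax, ref$cell, ref$crs, nodata = 0L)
}

#' Tiled merge
#'
#' Splits the grid into `tile_size` x `tile_size` blocks of cells, merges each
#' tile independently, and stitches the tiles back; bit-identical to
#' [merge_layers()] on the whole grid. Exists so very large study areas can
#' be processed piecewise.
#'
#' @inheritParams merge_layers
#' @param tile_size tile side length in cells (>= 1).
#' @return A [cat_raster()].
#' @export
tile_and_merge <- function(masks, reg, tile_size) {
  if (tile_size < 1) um_stop("tile_size must be >= 1")
  ref <- masks[[1]]
  nr <- nrow(ref$values); nc <- ncol(ref$values)
  out <- matrix(0L, nr, nc)
  row_starts <- seq(1L, nr, by = tile_size)
  col_starts <- seq(1L, nc, by = tile_size)
  for (r0 in row_starts) {
    r1 <- min(r0 + tile_size - 1L, nr)
    for (c0 in col_starts) {
      c1 <- min(c0 + tile_size - 1L, nc)
      sub <- lapply(masks, function(m) {
        cat_raster(m$values[r0:r1, c0:c1, drop = FALSE],
                   xmin = m$xmin + (c0 - 1L) * m$cell,
                   ymax = m$ymax - (r0 - 1L) * m$cell,
                   cell = m$cell, crs = m$crs, nodata = m$nodata)
      })
      merged <- merge_layers(sub, reg)
      out[r0:r1, c0:c1] <- merged$values
    }
  }
  cat_raster(out, ref$xmin, ref$ymax, ref$cell, ref$crs, nodata = 0L)
}

#' Reclassify a global land-cover raster into the framework legend
#'
#' Cell-wise lookup through a total map from the global product's legend to
#' framework class codes; "built/developed" global codes map to the
#' developed-unknown class 28 so that the absence of detailed features is
#' never mistaken for known land use.
#'
#' @param global_r the global [cat_raster()].
#' @param entries named integer vector, global code (name) -> framework code.
#' @param developed_codes global codes to send to class 28 (overrides
#'   `entries`).
#' @return A [cat_raster()] in the framework legend.
#' @export
reclass_global <- function(global_r, entries, developed_codes = integer()) {
  stopifnot(inherits(global_r, "cat_raster"))
  map <- entries
  if (length(developed_codes)) map[as.character(developed_codes)] <- 28L
  v <- global_r$values
  codes <- unique(v[v != global_r$nodata])
  unmapped <- setdiff(codes, as.integer(names(map)))
  if (length(unmapped)) {
    um_stop("global legend code(s) without a reclass entry: ",
            paste(sort(unmapped), collapse = ", "))
  }
  out <- matrix(global_r$nodata, nrow(v), ncol(v))
  for (gc in codes) out[v == gc] <- as.integer(map[[as.character(gc)]])
  cat_raster(out, global_r$xmin, global_r$ymax, global_r$cell, global_r$crs,
             nodata = global_r$nodata)
}

#' Backfill the merged raster from the reclassified global raster
#'
#' Any cell devoid of detailed information takes the (reclassified) global
#' land-cover class, so the output has no nodata wherever the global raster
#' is defined.
#'
#' @param osm_r merged framework [cat_raster()].
#' @param global_reclassed output of [reclass_global()] on the same grid.
#' @return A [cat_raster()].
#' @export
integrate_global <- function(osm_r, global_reclassed) {
  check_same_grid(osm_r, global_reclassed)
  out <- osm_r$values
  void <- out == osm_r$nodata
  out[void] <- global_reclassed$values[void]
  # global nodata cells stay nodata under the osm nodata code
  out[void & global_reclassed$values == global_reclassed$nodata] <- osm_r$nodata
  cat_raster(out, osm_r$xmin, osm_r$ymax, osm_r$cell, osm_r$crs,
             nodata = osm_r$nodata)
}

#' Nearest-neighbor alignment of a categorical raster to a working grid
#'
#' Categorical values cannot be interpolated; each target cell takes the
#' value of the source cell containing its center.
#'
#' @param r source [cat_raster()].
#' @param grid target [grid_spec()].
#' @return A [cat_raster()] on `grid`.
#' @export
align_to_grid <- function(r, grid) {
  stopifnot(inherits(r, "cat_raster"), inherits(grid, "grid_spec"))
  xs <- grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cell
  ys <- grid$ymax - (seq_len(grid$nrow) - 0.5) * grid$cell
  src_col <- floor((xs - r$xmin) / r$cell) + 1L
  src_row <- floor((r$ymax - ys) / r$cell) + 1L
  out <- matrix(r$nodata, grid$nrow, grid$ncol)
  ok_c <- src_col >= 1L & src_col <= ncol(r$values)
  ok_r <- src_row >= 1L & src_row <= nrow(r$values)
  for (i in which(ok_r)) {
    out[i, ok_c] <- r$values[src_row[i], src_col[ok_c]]
  }
  cat_raster(out, grid$xmin, grid$ymax, grid$cell, grid$crs,
             nodata = r$nodata, legend = r$legend)
}
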