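#' Categorical raster
#'
#' A rectangular grid of integer class codes with an affine georeference.
#' Row 1 is the top of the grid; the upper-left corner of cell (1, 1) sits at
#' `(xmin, ymax)` and cell `(row, col)` covers the half-open square
#' `[xmin + (col-1)*cell, xmin + col*cell) x (ymax - row*cell, ymax - (row-1)*cell]`.
#' Cell centers are at `xmin + (col - 0.5)*cell`, `ymax - (row - 0.5)*cell`.
#'
#' @param values integer matrix of class codes (row 1 = top).
#' @param xmin,ymax world coordinates of the grid's upper-left corner (m).
#' @param cell cell size in meters (> 0).
#' @param crs projected CRS identifier (e.g. `"EPSG:32616"`).
#' @param nodata integer code marking empty cells; must not appear in `legend`.
#' @param legend named character vector mapping code (name) to class name.
#' @return An object of class `cat_raster`.
#' @export
cat_raster <- function(values, xmin, ymax, cell, crs,
                       nodata = 0L, legend = NULL) {
  if (!is.matrix(values)) um_stop("values must be a matrix")
  if (cell <= 0) um_stop("cell size must be > 0")
  storage.mode(values) <- "integer"
  nodata <- as.integer(nodata)
  if (!is.null(legend)) {
    if (is.null(names(legend))) um_stop("legend must be named by code")
    if (as.character(nodata) %in% names(legend)) {
      um_stop("legend code ", nodata, " collides with the nodata code")
    }
    codes <- unique(values[values != nodata])
    bad <- setdiff(codes, as.integer(names(legend)))
    if (length(bad)) {
      um_stop("cell codes absent from legend: ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cell = as.numeric(cell), crs = crs, nodata = nodata, legend = legend),
    class = "cat_raster"
  )
}

#' Continuous (floating point) raster on the same grid convention
#'
#' @inheritParams cat_raster
#' @param values numeric matrix (NA marks empty cells).
#' @return An object of class `num_raster`.
#' @export
num_raster <- function(values, xmin, ymax, cell, crs) {
  if (!is.matrix(values)) um_stop("values must be a matrix")
  if (cell <= 0) um_stop("cell size must be > 0")
  storage.mode(values) <- "double"
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cell = as.numeric(cell), crs = crs),
    class = "num_raster"
  )
}

#' @export
print.cat_raster <- function(x, ...) {
  cat("<cat_raster> ", nrow(x$values), "x", ncol(x$values),
      " cells @ ", x$cell, " m, crs ", x$crs %||% "<none>", "\n", sep = "")
  tab <- table(x$values)
  cat("  codes:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' @export
print.num_raster <- function(x, ...) {
  cat("<num_raster> ", nrow(x$values), "x", ncol(x$values),
      " cells @ ", x$cell, " m, range [",
      paste(signif(range(x$values, na.rm = TRUE), 5), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

raster_dim <- function(r) dim(r$values)

# x coordinates of column centers / y coordinates of row centers
cell_center_x <- function(r) r$xmin + (seq_len(ncol(r$values)) - 0.5) * r$cell
cell_center_y <- function(r) r$ymax - (seq_len(nrow(r$values)) - 0.5) * r$cell

same_grid <- function(a, b) {
  all(dim(a$values) == dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymax, a$cell), c(b$xmin, b$ymax, b$cell)))
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!same_grid(a, b)) um_stop(what, " are not on the same grid")
  invisible(TRUE)
}

#' Write / read a raster as ESRI ASCII Grid with a JSON metadata sidecar
#'
#' The grid goes to `path` in the plain-text ESRI ASCII Grid (`.asc`) format;
#' the CRS, legend and value type go to `<path>.json`. Integer rasters
#' round-trip bit-identically; continuous rasters are written with 17
#' significant digits (exact for doubles).
#'
#' @param r a [cat_raster()] or [num_raster()].
#' @param path output file path.
#' @return `write_raster` returns `path` invisibly; `read_raster` returns the
#'   raster object.
#' @export
write_raster <- function(r, path) {
  is_cat <- inherits(r, "cat_raster")
  if (!is_cat && !inherits(r, "num_raster")) {
    um_stop("r must be a cat_raster or num_raster")
  }
  nr <- nrow(r$values); nc <- ncol(r$values)
  nodata <- if (is_cat) r$nodata else -9999
  vals <- r$values
  if (!is_cat) vals[is.na(vals)] <- nodata
  hdr <- c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(r$xmin, digits = 17)),
    paste("yllcorner", format(r$ymax - nr * r$cell, digits = 17)),
    paste("cellsize", format(r$cell, digits = 17)),
    paste("NODATA_value", nodata)
  )
  rows <- apply(vals, 1, function(v) {
    paste(if (is_cat) as.character(v) else formatC(v, digits = 17, format = "g"),
          collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  meta <- list(
    crs = r$crs,
    type = if (is_cat) "categorical" else "continuous",
    nodata = nodata,
    legend = if (is_cat && !is.null(r$legend)) as.list(r$legend) else NULL
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) um_stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    strsplit(trimws(ln), "\\s+")[[1]][2]
  }
  nc <- as.integer(val("ncols")); nr <- as.integer(val("nrows"))
  xll <- as.numeric(val("xllcorner")); yll <- as.numeric(val("yllcorner"))
  cell <- as.numeric(val("cellsize")); nodata <- as.numeric(val("NODATA_value"))
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(type = "categorical", crs = NULL)
  vals <- do.call(rbind, lapply(body, function(ln) {
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }))
  if (!all(dim(vals) == c(nr, nc))) um_stop("raster body does not match header")
  ymax <- yll + nr * cell
  if (identical(meta$type, "continuous")) {
    vals[vals == nodata] <- NA_real_
    num_raster(vals, xll, ymax, cell, crs = meta$crs)
  } else {
    legend <- if (!is.null(meta$legend) && length(meta$legend)) {
      unlist(meta$legend)
    } else NULL
    cat_raster(vals, xll, ymax, cell, crs = meta$crs,
               nodata = as.integer(nodata), legend = legend)
  }
}

#' Areal tally of class codes
#'
#' @param r a [cat_raster()].
#' @param codes codes to tally; defaults to all non-nodata codes present.
#' @return named numeric vector of areas in square meters.
#' @export
class_areas <- function(r, codes = NULL) {
  stopifnot(inherits(r, "cat_raster"))
  v <- r$values[r$values != r$nodata]
  if (is.null(codes)) codes <- sort(unique(v))
  counts <- vapply(codes, function(cd) sum(v == cd), 0L)
  stats::setNames(counts * r$cell^2, codes)
}
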