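#' @keywords internal
"_PACKAGE"

# inverse logit on the numerically safe branch
invlogit <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

logit <- function(p) log(p) - log1p(-p)

`%||%` <- function(a, b) if (is.null(a)) b else a

um_warn <- function(...) warning(paste0(...), call. = FALSE)
um_stop <- function(...) stop(paste0(...), call. = FALSE)

# bbox: named numeric c(xmin, ymin, xmax, ymax)
check_bbox <- function(bbox) {
  if (length(bbox) != 4 || any(!is.finite(bbox))) {
    um_stop("bbox must be four finite numbers (xmin, ymin, xmax, ymax)")
  }
  bbox <- as.numeric(bbox)
  names(bbox) <- c("xmin", "ymin", "xmax", "ymax")
  if (bbox["xmax"] <= bbox["xmin"] || bbox["ymax"] <= bbox["ymin"]) {
    um_stop("degenerate bbox: sides must have positive length")
  }
  bbox
}

# CRS identifiers known to be geographic (degree units): processing requires
# a projected CRS because buffer widths are in meters.
is_geographic_crs <- function(crs) {
  if (is.null(crs) || !nzchar(crs)) return(FALSE)
  grepl("4326|4267|4269|CRS84|longlat|WGS *84$", crs, ignore.case = TRUE)
}

check_projected_crs <- function(crs) {
  if (is.null(crs) || !nzchar(crs)) {
    um_stop(
      "no CRS declared; declare a projected, meter-unit CRS ",
      "(e.g. \"EPSG:32616\") via the crs argument or a GeoJSON crs member"
    )
  }
  if (is_geographic_crs(crs)) {
    um_stop(
      "CRS '", crs, "' is geographic (degree units); reproject to a ",
      "projected meter-unit CRS before processing - buffering in meters ",
      "is meaningless in degrees"
    )
  }
  invisible(crs)
}
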