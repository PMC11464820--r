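#' Classify tagged features into land-cover classes
#'
#' Evaluates every registry rule against every feature. A feature appears
#' under every class whose predicates it satisfies (multi-membership is
#' deliberate: overlaps are resolved later by raster priority, not by vector
#' precedence). Features matching no rule land in the `"unclassified"` bin
#' for diagnostics. Membership is independent of input order.
#'
#' @param fc a [tagged_features()] collection.
#' @param reg a [class_registry()].
#' @return Named list: one [tagged_features()] per matched class code
#'   (names are the codes), plus `"unclassified"`.
#' @export
classify_features <- function(fc, reg) {
  stopifnot(inherits(fc, "tagged_features"), inherits(reg, "class_registry"))
  out <- list()
  unclassified <- list()
  for (f in fc$features) {
    kind <- if (f$geometry$type == "polygon") "polygon" else "line"
    hit <- FALSE
    for (r in reg$rules) {
      if (r$geometry_kind != kind) next
      if (rule_matches(r, f$tags)) {
        key <- as.character(r$code)
        out[[key]] <- c(out[[key]], list(f))
        hit <- TRUE
      }
    }
    if (!hit) unclassified <- c(unclassified, list(f))
  }
  res <- lapply(out, tagged_features, crs = fc$crs)
  res <- res[order(as.integer(names(res)))]
  res$unclassified <- tagged_features(unclassified, fc$crs)
  res
}

# lanes tag -> numeric, NA when unparseable
parse_lanes <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v <= 0) NA_real_ else v
}

buffer_width_for <- function(f, spec) {
  if (!is.null(spec$fixed_width)) return(spec$fixed_width)
  lanes <- NA_real_
  if ("lanes" %in% names(f$tags)) {
    lanes <- parse_lanes(f$tags[["lanes"]])
    if (is.na(lanes)) {
      message("feature ", f$id, ": unparseable lanes tag '",
              f$tags[["lanes"]], "', using the type default")
    }
  }
  if (is.na(lanes)) lanes <- spec$default_lanes
  if (is.null(lanes) || is.na(lanes)) {
    um_stop("no lane count available for feature ", f$id,
            " and no fixed width in its buffer spec")
  }
  lanes * spec$meters_per_lane
}

#' Buffer linear features into polygons
#'
#' Each line is replaced by a flat-capped polygon of total width
#' `lanes x meters_per_lane`, where the lane count comes from the feature's
#' `lanes` tag when parseable and otherwise from the mean lane count of its
#' road type; classes with a `fixed_width` (paths, railways, fences) use that
#' width regardless of lanes. Tags are preserved. Zero-length lines are
#' dropped with a warning.
#'
#' @param lines a [tagged_features()] collection of line features, all
#'   matching some line rule of `reg`.
#' @param reg a [class_registry()] supplying buffer specs.
#' @return A [tagged_features()] collection of polygons.
#' @export
buffer_lines <- function(lines, reg) {
  stopifnot(inherits(lines, "tagged_features"), inherits(reg, "class_registry"))
  out <- list()
  for (f in lines$features) {
    if (f$geometry$type != "line") {
      um_stop("buffer_lines expects line features; feature ", f$id,
              " is a ", f$geometry$type)
    }
    rule <- NULL
    for (r in reg$rules) {
      if (r$geometry_kind == "line" && rule_matches(r, f$tags)) {
        rule <- r
        break
      }
    }
    if (is.null(rule)) {
      um_stop("feature ", f$id, " has no recognized linear type tag")
    }
    spec <- reg$buffers[[as.character(rule$code)]]
    if (is.null(spec)) {
      um_stop("no buffer spec for line class ", rule$code,
              " (", rule$name, ")")
    }
    width <- buffer_width_for(f, spec)
    if (width <= 0) um_stop("buffer width must be > 0 for feature ", f$id)
    if (geom_length(f$geometry) == 0) {
      um_warn("feature ", f$id, " has zero length; dropped")
      next
    }
    g <- buffer_line_geom(f$geometry, width)
    if (is.null(g)) {
      um_warn("feature ", f$id, " produced an empty buffer; dropped")
      next
    }
    f$geometry <- g
    out[[length(out) + 1]] <- f
  }
  tagged_features(out, lines$crs)
}
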