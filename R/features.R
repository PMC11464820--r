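#' Tagged feature collections
#'
#' A `tagged_features` object is an ordered list of features, each a list with
#' `id` (string), `geometry` (a polygon or line in the package's planar
#' geometry representation) and `tags` (named character vector, lowercase
#' keys), plus a shared projected CRS. This is the vector currency of the
#' whole pipeline: classification rules only ever see the flat tag map.
#'
#' @param features list of features (each `list(id, geometry, tags)`).
#' @param crs projected CRS identifier shared by all features.
#' @return An object of class `tagged_features`.
#' @export
tagged_features <- function(features, crs) {
  check_projected_crs(crs)
  ids <- vapply(features, function(f) f$id, "")
  if (anyDuplicated(ids)) um_stop("feature ids must be unique in a collection")
  structure(list(features = features, crs = crs), class = "tagged_features")
}

#' Construct one tagged feature
#'
#' @param id feature identifier.
#' @param geometry polygon or line geometry (see [geom_polygon()]).
#' @param tags named character vector; keys are lowercased, duplicate keys
#'   collapse to the first occurrence.
#' @return A feature list suitable for [tagged_features()].
#' @export
tagged_feature <- function(id, geometry, tags = character()) {
  tags <- normalize_tags(tags)
  list(id = as.character(id), geometry = geometry, tags = tags)
}

normalize_tags <- function(tags) {
  if (!length(tags)) return(stats::setNames(character(0), character(0)))
  keys <- tolower(names(tags))
  vals <- as.character(tags)
  keep <- !duplicated(keys) & !is.na(vals) & nzchar(keys)
  stats::setNames(vals[keep], keys[keep])
}

#' @export
print.tagged_features <- function(x, ...) {
  cat("<tagged_features> ", length(x$features), " features, crs ",
      x$crs, "\n", sep = "")
  invisible(x)
}

#' @export
length.tagged_features <- function(x) length(x$features)

n_features <- function(fc) length(fc$features)

#' Unpack the packed auxiliary-tag string dialect
#'
#' The OSM extract dialect packs uncolumned tags into one string field of the
#' form `"key"=>"value","key2"=>"value2"`. Unparseable fragments are skipped
#' with a message.
#'
#' @param packed a single packed string (or NA/empty).
#' @return Named character vector of tags (possibly empty).
#' @export
unpack_tags <- function(packed) {
  empty <- stats::setNames(character(0), character(0))
  if (is.null(packed) || is.na(packed) || !nzchar(packed)) return(empty)
  m <- gregexpr('"((?:[^"\\\\]|\\\\.)*)"\\s*=>\\s*"((?:[^"\\\\]|\\\\.)*)"',
                packed, perl = TRUE)[[1]]
  if (m[1] == -1) {
    message("packed tag string had no parseable \"k\"=>\"v\" fragments")
    return(empty)
  }
  frags <- regmatches(packed, gregexpr(
    '"((?:[^"\\\\]|\\\\.)*)"\\s*=>\\s*"((?:[^"\\\\]|\\\\.)*)"', packed,
    perl = TRUE))[[1]]
  kv <- lapply(frags, function(fr) {
    parts <- regmatches(fr, regexec(
      '"((?:[^"\\\\]|\\\\.)*)"\\s*=>\\s*"((?:[^"\\\\]|\\\\.)*)"', fr,
      perl = TRUE))[[1]]
    c(parts[2], parts[3])
  })
  consumed <- sum(nchar(frags)) + (length(frags) - 1)  # commas between
  if (consumed < nchar(gsub("\\s", "", packed)) - 2) {
    message("some fragments of a packed tag string were not parseable; skipped")
  }
  normalize_tags(stats::setNames(
    vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1)))
}

# --- GeoJSON ----------------------------------------------------------------

geojson_crs <- function(obj, crs = NULL) {
  if (!is.null(crs)) return(crs)
  cm <- obj$crs
  if (is.character(cm)) return(cm)
  if (is.list(cm) && !is.null(cm$properties$name)) {
    nm <- cm$properties$name
    code <- regmatches(nm, regexpr("[0-9]+$", nm))
    if (length(code) && grepl("EPSG", nm, ignore.case = TRUE)) {
      return(paste0("EPSG:", code))
    }
    return(nm)
  }
  NULL
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
}

#' Read tagged features from GeoJSON
#'
#' Reads a GeoJSON `FeatureCollection`, keeping only the requested geometry
#' kind. Multi-geometries are exploded into single parts that share the parent
#' id with a `#<part>` suffix. A packed auxiliary-tag field (default
#' `other_tags`, the `"k"=>"v"` extract dialect) is unpacked into the flat tag
#' map; explicit property columns win on key collision. Strict GeoJSON
#' mandates geographic WGS84 coordinates, but this pipeline needs meter units,
#' so a projected CRS must be declared either through a (non-RFC) `crs` member
#' in the file or the `crs` argument; geographic CRSs are rejected.
#'
#' @param source path to a GeoJSON file.
#' @param geometry_kind `"polygons"` or `"lines"`.
#' @param crs optional CRS override for files without a `crs` member.
#' @param packed_key property holding packed auxiliary tags.
#' @return A [tagged_features()] collection.
#' @export
read_features <- function(source, geometry_kind = c("polygons", "lines"),
                          crs = NULL, packed_key = "other_tags") {
  geometry_kind <- match.arg(geometry_kind)
  if (!file.exists(source)) um_stop("no such file: ", source)
  obj <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  crs <- geojson_crs(obj, crs)
  check_projected_crs(crs)
  want <- if (geometry_kind == "polygons") c("Polygon", "MultiPolygon")
          else c("LineString", "MultiLineString")
  feats <- list()
  raw <- obj$features %||% list()
  for (i in seq_along(raw)) {
    f <- raw[[i]]
    if (is.null(f$geometry) || is.null(f$geometry$type)) {
      um_warn("feature ", i, " has no geometry; skipped")
      next
    }
    gtype <- f$geometry$type
    if (!gtype %in% want) next
    props <- f$properties %||% list()
    props <- props[!vapply(props, is.null, TRUE)]
    tags <- normalize_tags(unlist(lapply(props, as.character)))
    if (tolower(packed_key) %in% names(tags)) {
      packed <- unpack_tags(tags[[tolower(packed_key)]])
      tags <- tags[names(tags) != tolower(packed_key)]
      extra <- packed[!names(packed) %in% names(tags)]
      tags <- c(tags, extra)
    }
    id <- as.character(props$id %||% props$osm_id %||% f$id %||% paste0("f", i))
    tags <- tags[!names(tags) %in% c("id", "osm_id")]
    geoms <- switch(gtype,
      Polygon = list(geom_polygon(lapply(f$geometry$coordinates,
                                         coords_to_matrix))),
      MultiPolygon = lapply(f$geometry$coordinates, function(part) {
        geom_polygon(lapply(part, coords_to_matrix))
      }),
      LineString = list(geom_line(coords_to_matrix(f$geometry$coordinates))),
      MultiLineString = lapply(f$geometry$coordinates, function(part) {
        geom_line(coords_to_matrix(part))
      })
    )
    multi <- length(geoms) > 1
    for (k in seq_along(geoms)) {
      g <- repair_geom(geoms[[k]])
      if (is.null(g)) {
        um_warn("feature ", id, " invalid after repair; dropped")
        next
      }
      fid <- if (multi) paste0(id, "#", k) else id
      feats[[length(feats) + 1]] <- list(id = fid, geometry = g, tags = tags)
    }
  }
  ids <- vapply(feats, function(f) f$id, "")
  if (anyDuplicated(ids)) {
    dup <- ids %in% ids[duplicated(ids)]
    for (j in which(dup)) feats[[j]]$id <- paste0(feats[[j]]$id, "#", j)
  }
  tagged_features(feats, crs)
}

# Degenerate rings (near-zero area or < 4 vertices) are dropped; a feature
# left with no valid rings/parts is invalid.
repair_geom <- function(g) {
  if (g$type == "polygon") {
    parts <- list()
    for (part in g$parts) {
      rings <- Filter(function(r) nrow(r) >= 4 && all(is.finite(r)) &&
                        abs(ring_area_signed(r)) > 0, lapply(part, close_ring))
      if (length(rings)) parts[[length(parts) + 1]] <- rings
    }
    if (!length(parts)) return(NULL)
    list(type = "polygon", parts = parts)
  } else {
    parts <- Filter(function(m) nrow(m) >= 2 && all(is.finite(m)) &&
                      path_length(m) > 0, g$parts)
    if (!length(parts)) return(NULL)
    list(type = "line", parts = parts)
  }
}

#' Write tagged features to GeoJSON
#'
#' Single-part geometries are written as `Polygon`/`LineString`, multi-part as
#' their `Multi*` counterparts. The projected CRS goes into a (non-RFC) named
#' `crs` member so [read_features()] round-trips it.
#'
#' @param fc a [tagged_features()] collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fc, path) {
  stopifnot(inherits(fc, "tagged_features"))
  feat_json <- lapply(fc$features, function(f) {
    g <- f$geometry
    geom <- if (g$type == "polygon") {
      coords <- lapply(g$parts, function(part) {
        lapply(part, function(r) lapply(seq_len(nrow(r)),
                                        function(i) as.numeric(r[i, ])))
      })
      if (length(coords) == 1) {
        list(type = "Polygon", coordinates = coords[[1]])
      } else list(type = "MultiPolygon", coordinates = coords)
    } else {
      coords <- lapply(g$parts, function(m) {
        lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
      })
      if (length(coords) == 1) {
        list(type = "LineString", coordinates = coords[[1]])
      } else list(type = "MultiLineString", coordinates = coords)
    }
    props <- c(list(id = f$id), as.list(f$tags))
    list(type = "Feature", properties = props, geometry = geom)
  })
  obj <- list(
    type = "FeatureCollection",
    crs = list(type = "name", properties = list(name = fc$crs)),
    features = feat_json
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Clip a feature collection to a bounding box
#'
#' Features intersecting the box are kept and geometrically clipped to it;
#' features entirely outside are dropped. Clipping twice with the same box is
#' a no-op.
#'
#' @param fc a [tagged_features()] collection.
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` in the collection's CRS.
#' @return The clipped collection.
#' @export
clip_to_bbox <- function(fc, bbox) {
  stopifnot(inherits(fc, "tagged_features"))
  bbox <- check_bbox(bbox)
  out <- list()
  for (f in fc$features) {
    g <- clip_geom_rect(f$geometry, bbox)
    if (is.null(g)) next
    f$geometry <- g
    out[[length(out) + 1]] <- f
  }
  tagged_features(out, fc$crs)
}
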