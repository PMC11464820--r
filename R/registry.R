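#' Classification rule registry
#'
#' A `class_registry` holds the ordered classification rules mapping tag
#' predicates to land-cover classes, the priority rank of every class (higher
#' rank wins the raster overlay), and the buffer specifications used to turn
#' linear features into polygons. The registry is data, not code: it can be
#' serialized to YAML, edited, and reloaded, so published tag tables can be
#' substituted for the defaults.
#'
#' @param rules list of rules; each rule is a list with `code` (integer),
#'   `name`, `category` (`"land_use"`, `"green_cover"` or `"infrastructure"`),
#'   `geometry_kind` (`"polygon"` or `"line"`) and `predicates` (list of
#'   `list(key =, values =)`; `values = "*"` matches any value).
#' @param priority named integer vector, code -> rank (higher wins); must
#'   cover every rule code plus the developed-unknown code 28.
#' @param buffers named list, class code -> `list(meters_per_lane,
#'   default_lanes, fixed_width)` for line classes.
#' @return An object of class `class_registry`.
#' @export
class_registry <- function(rules, priority, buffers = list()) {
  if (!length(rules)) um_stop("registry must contain at least one rule")
  codes <- vapply(rules, function(r) as.integer(r$code), 0L)
  if (anyDuplicated(codes)) um_stop("duplicate class codes in registry rules")
  for (r in rules) {
    if (!length(r$predicates)) {
      um_stop("rule for class ", r$code, " has no predicates")
    }
  }
  need <- c(codes, 28L)
  miss <- setdiff(need, as.integer(names(priority)))
  if (length(miss)) {
    um_stop("priority rank missing for classes: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(priority[as.character(need)])) {
    um_stop("priority ranks must be unique")
  }
  structure(list(rules = rules, priority = priority, buffers = buffers),
            class = "class_registry")
}

#' @export
print.class_registry <- function(x, ...) {
  cat("<class_registry> ", length(x$rules), " rules, ",
      length(x$priority), " priority ranks, ",
      length(x$buffers), " buffer specs\n", sep = "")
  invisible(x)
}

registry_codes <- function(reg) {
  vapply(reg$rules, function(r) as.integer(r$code), 0L)
}

registry_rule <- function(reg, code) {
  for (r in reg$rules) if (r$code == code) return(r)
  NULL
}

#' Class codes counted as urban (developed) surface
#'
#' Classes in the land-use and infrastructure categories, plus the
#' developed-unknown class 28.
#'
#' @param reg a [class_registry()].
#' @return integer vector of class codes.
#' @export
urban_codes <- function(reg) {
  codes <- vapply(
    Filter(function(r) r$category %in% c("land_use", "infrastructure"),
           reg$rules),
    function(r) as.integer(r$code), 0L)
  sort(c(codes, 28L))
}

rule_matches <- function(rule, tags) {
  for (p in rule$predicates) {
    key <- tolower(p$key)
    if (!key %in% names(tags)) next
    if (identical(p$values, "*") ||
        tolower(tags[[key]]) %in% tolower(p$values)) {
      return(TRUE)
    }
  }
  FALSE
}

pred <- function(key, values) list(key = key, values = values)

#' Default 27-class registry
#'
#' A documented reconstruction of the three-category urban land-cover
#' framework: human land use (by activity type), green cover (by vegetation
#' density and management, plus water and barren soil), and infrastructure
#' (buildings, parking, roads by type, railways, paths, fences). Codes 7
#' (protected area, vegetation type unknown), 17 (road type unknown), 26
#' (linear feature under construction or abandoned) and 28 (developed
#' unknown, assigned only from the global backfill) keep their diagnostic
#' roles. Priorities place land use lowest, green cover above it, water and
#' barren above vegetation, then buildings and parking, then roads in
#' ascending traffic order, and hiking paths, railways and fences above all.
#' Road buffers use 6 m per lane with a per-type mean lane count used
#' whenever a feature lacks a parseable `lanes` tag.
#'
#' @param meters_per_lane buffer width per road lane, meters.
#' @return A [class_registry()].
#' @export
default_registry <- function(meters_per_lane = 6) {
  rules <- list(
    list(code = 1L, name = "residential", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", "residential"))),
    list(code = 2L, name = "commercial", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", c("commercial", "retail")))),
    list(code = 3L, name = "industrial", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", c("industrial", "railway")),
                           pred("industrial", "*"))),
    list(code = 4L, name = "institutional", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(
           pred("landuse", c("institutional", "education", "religious")),
           pred("amenity", c("school", "university", "college", "hospital",
                             "place_of_worship")))),
    list(code = 5L, name = "recreation", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", "recreation_ground"),
                           pred("leisure", c("pitch", "stadium",
                                             "sports_centre", "playground")))),
    list(code = 6L, name = "cemetery", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", "cemetery"),
                           pred("amenity", "grave_yard"))),
    list(code = 7L, name = "protected_green", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("boundary", c("protected_area",
                                              "national_park")),
                           pred("leisure", "nature_reserve"))),
    list(code = 8L, name = "forest", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", "forest"),
                           pred("natural", "wood"))),
    list(code = 9L, name = "low_vegetation", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", c("grass", "meadow")),
                           pred("natural", c("grassland", "scrub", "heath")))),
    list(code = 10L, name = "open_green", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("leisure", c("park", "garden", "golf_course",
                                             "dog_park")),
                           pred("landuse", "village_green"))),
    list(code = 11L, name = "barren", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("natural", c("sand", "bare_rock", "beach",
                                             "scree", "shingle")),
                           pred("landuse", "brownfield"))),
    list(code = 12L, name = "water", category = "green_cover",
         geometry_kind = "polygon",
         predicates = list(pred("natural", "water"),
                           pred("landuse", c("reservoir", "basin")),
                           pred("water", "*"))),
    list(code = 13L, name = "buildings", category = "infrastructure",
         geometry_kind = "polygon",
         predicates = list(pred("building", "*"))),
    list(code = 14L, name = "parking", category = "infrastructure",
         geometry_kind = "polygon",
         predicates = list(pred("amenity", "parking"),
                           pred("landuse", "garages"))),
    list(code = 15L, name = "motorway", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("motorway", "motorway_link",
                                             "trunk", "trunk_link")))),
    list(code = 16L, name = "primary_road", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("primary", "primary_link")))),
    list(code = 17L, name = "road_unknown", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("unclassified", "road")))),
    list(code = 18L, name = "secondary_road", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("secondary", "secondary_link")))),
    list(code = 19L, name = "tertiary_road", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("tertiary", "tertiary_link")))),
    list(code = 20L, name = "residential_road", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("residential",
                                             "living_street")))),
    list(code = 21L, name = "service_road", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", "service"))),
    list(code = 22L, name = "hiking_path", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", c("path", "footway", "track",
                                             "cycleway", "bridleway")))),
    list(code = 23L, name = "railway", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("railway", c("rail", "light_rail", "subway",
                                             "tram")))),
    list(code = 24L, name = "fence", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("barrier", c("fence", "wall", "hedge")))),
    list(code = 25L, name = "construction_site", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", "construction"))),
    list(code = 26L, name = "construction_linear", category = "infrastructure",
         geometry_kind = "line",
         predicates = list(pred("highway", "construction"),
                           pred("railway", c("construction", "abandoned",
                                             "disused")))),
    list(code = 27L, name = "agriculture", category = "land_use",
         geometry_kind = "polygon",
         predicates = list(pred("landuse", c("farmland", "orchard",
                                             "allotments", "vineyard"))))
  )
  # rank order (low -> high): developed-unknown, land use, green cover,
  # barren/water, buildings, parking, roads ascending traffic,
  # construction-linear, hiking paths, railway, fence
  rank_order <- c(28L,                       # developed unknown (backfill)
                  1L, 2L, 3L, 4L, 5L, 6L, 25L, 27L,   # land use
                  7L, 8L, 9L, 10L,           # vegetation
                  11L, 12L,                  # barren, water
                  13L, 14L,                  # buildings, parking
                  21L, 20L, 17L, 19L, 18L, 16L, 15L,  # roads, ascending
                  26L, 22L, 23L, 24L)        # construction, path, rail, fence
  priority <- stats::setNames(seq_along(rank_order) - 1L,
                              as.character(rank_order))
  buf <- function(default_lanes = NULL, fixed_width = NULL) {
    list(meters_per_lane = meters_per_lane, default_lanes = default_lanes,
         fixed_width = fixed_width)
  }
  buffers <- list(
    "15" = buf(default_lanes = 4),
    "16" = buf(default_lanes = 3),
    "17" = buf(default_lanes = 2),
    "18" = buf(default_lanes = 2),
    "19" = buf(default_lanes = 2),
    "20" = buf(default_lanes = 2),
    "21" = buf(default_lanes = 1),
    "22" = buf(fixed_width = 2),
    "23" = buf(fixed_width = 6),
    "24" = buf(fixed_width = 1),
    "26" = buf(default_lanes = 2)
  )
  class_registry(rules, priority, buffers)
}

#' Serialize / load a registry as YAML
#'
#' @param reg a [class_registry()].
#' @param path YAML file path.
#' @return `write_registry` returns `path` invisibly; `read_registry` the
#'   registry.
#' @export
write_registry <- function(reg, path) {
  obj <- list(
    rules = lapply(reg$rules, function(r) {
      r$code <- as.integer(r$code)
      r
    }),
    priority = as.list(reg$priority),
    buffers = reg$buffers
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  obj <- yaml::read_yaml(path)
  rules <- lapply(obj$rules, function(r) {
    r$code <- as.integer(r$code)
    r$predicates <- lapply(r$predicates, function(p) {
      list(key = p$key, values = unlist(p$values))
    })
    r
  })
  priority <- stats::setNames(as.integer(unlist(obj$priority)),
                              names(obj$priority))
  class_registry(rules, priority, obj$buffers %||% list())
}
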