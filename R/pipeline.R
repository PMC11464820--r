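#' Pipeline run configuration
#'
#' Bundles every input path and setting one coherent run needs. Paths are
#' checked lazily, when the stage that needs them runs.
#'
#' @param features path to a GeoJSON file holding the tagged features
#'   (polygons and lines together).
#' @param global_raster path to the coarse global land-cover raster (ASCII
#'   grid) or `NULL` to skip integration.
#' @param out_dir output directory (created if absent).
#' @param grid a [grid_spec()], or `NULL` to derive a 30 m grid from the
#'   feature extent.
#' @param registry a [class_registry()] or path to a registry YAML.
#' @param reclass list with `entries` and `developed_codes` (see
#'   [default_reclass_map()]).
#' @param index_cfg an [index_config()].
#' @param detections,sites paths to the detection-records and site CSVs.
#' @param seed integer seed used by every stochastic stage.
#' @param crs CRS override for feature files without a crs member.
#' @return An object of class `run_config`.
#' @export
run_config <- function(features = NULL, global_raster = NULL,
                       out_dir = "urbanmosaic_out", grid = NULL,
                       registry = default_registry(),
                       reclass = default_reclass_map(),
                       index_cfg = index_config(),
                       detections = NULL, sites = NULL,
                       seed = 1L, crs = NULL) {
  if (is.character(registry)) registry <- read_registry(registry)
  structure(list(features = features, global_raster = global_raster,
                 out_dir = out_dir, grid = grid, registry = registry,
                 reclass = reclass, index_cfg = index_cfg,
                 detections = detections, sites = sites,
                 seed = as.integer(seed), crs = crs),
            class = "run_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".rds")
  on.exit(unlink(tmp))
  keep <- cfg[setdiff(names(cfg), "out_dir")]
  saveRDS(keep, tmp, version = 2)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  man <- list(stage = stage,
              inputs = inputs,
              outputs = outputs,
              seed = cfg$seed,
              config_md5 = config_hash(cfg),
              package_version = as.character(utils::packageVersion("urbanmosaic")))
  path <- file.path(cfg$out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null")
  path
}

read_all_features <- function(cfg) {
  if (is.null(cfg$features)) um_stop("config has no features path")
  polys <- read_features(cfg$features, "polygons", crs = cfg$crs)
  lines <- read_features(cfg$features, "lines", crs = cfg$crs)
  tagged_features(c(polys$features, lines$features), polys$crs)
}

pipeline_grid <- function(cfg, fc) {
  if (!is.null(cfg$grid)) return(cfg$grid)
  bbs <- lapply(fc$features, function(f) geom_bbox(f$geometry))
  bb <- c(min(vapply(bbs, `[`, 0, "xmin")), min(vapply(bbs, `[`, 0, "ymin")),
          max(vapply(bbs, `[`, 0, "xmax")), max(vapply(bbs, `[`, 0, "ymax")))
  grid_spec(bb, 30, fc$crs)
}

#' Run pipeline stages
#'
#' Wires the framework end to end: `classify` (per-class GeoJSON layers),
#' `build` (buffer, rasterize, priority-merge into the detail raster),
#' `integrate` (reclassify the global raster and backfill),
#' `validate` (completeness report), `index` (urbanization index raster) and
#' `occupancy` (autologistic model competition at camera sites). Each stage
#' writes its artifacts plus a JSON manifest (inputs, seed, config hash,
#' package version) under the run's output directory; stages never mutate
#' their inputs, and deterministic stages are bit-identical under rerun.
#' Later stages read the artifacts of earlier ones and name the missing
#' stage when a dependency has not been run.
#'
#' @param cfg a [run_config()].
#' @param stages character subset of
#'   `c("classify", "build", "integrate", "validate", "index", "occupancy")`.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(cfg, stages = c("classify", "build", "integrate",
                                         "validate", "index", "occupancy")) {
  stopifnot(inherits(cfg, "run_config"))
  all_stages <- c("classify", "build", "integrate", "validate", "index",
                  "occupancy")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  reg <- cfg$registry
  artifacts <- list()
  need <- function(path, stage_needed) {
    if (!file.exists(path)) {
      um_stop("missing artifact ", path, "; run the '", stage_needed,
              "' stage first")
    }
    path
  }

  if ("classify" %in% stages) {
    fc <- read_all_features(cfg)
    message("classify: ", n_features(fc), " features in")
    layers <- classify_features(fc, reg)
    cdir <- file.path(cfg$out_dir, "classify")
    dir.create(cdir, showWarnings = FALSE)
    outs <- character()
    for (nm in names(layers)) {
      p <- file.path(cdir, paste0("class_", nm, ".geojson"))
      write_features(layers[[nm]], p)
      outs <- c(outs, p)
      message("classify: class ", nm, " <- ", n_features(layers[[nm]]),
              " features")
    }
    artifacts$classify <- outs
    write_manifest(cfg, "classify", cfg$features, outs)
  }

  if ("build" %in% stages) {
    cdir <- file.path(cfg$out_dir, "classify")
    need(cdir, "classify")
    fc <- read_all_features(cfg)
    grid <- pipeline_grid(cfg, fc)
    lulc <- build_lulc(fc, grid, reg)
    message("build: ", sum(lulc$values != lulc$nodata), " of ",
            length(lulc$values), " cells classified")
    p <- file.path(cfg$out_dir, "lulc_osm.asc")
    write_raster(lulc, p)
    artifacts$build <- p
    write_manifest(cfg, "build", cfg$features, p)
  }

  if ("integrate" %in% stages) {
    osm_p <- need(file.path(cfg$out_dir, "lulc_osm.asc"), "build")
    if (is.null(cfg$global_raster)) {
      um_stop("config has no global_raster path; integration impossible")
    }
    osm_r <- read_raster(osm_p)
    glob <- read_raster(cfg$global_raster)
    grid <- grid_spec(c(osm_r$xmin, osm_r$ymax - nrow(osm_r$values) * osm_r$cell,
                        osm_r$xmin + ncol(osm_r$values) * osm_r$cell,
                        osm_r$ymax), osm_r$cell, osm_r$crs)
    glob <- align_to_grid(glob, grid)
    reclassed <- reclass_global(glob, cfg$reclass$entries,
                                cfg$reclass$developed_codes)
    full <- integrate_global(osm_r, reclassed)
    message("integrate: ", sum(osm_r$values == osm_r$nodata),
            " void cells backfilled from the global raster")
    p <- file.path(cfg$out_dir, "lulc.asc")
    write_raster(full, p)
    artifacts$integrate <- p
    write_manifest(cfg, "integrate", c(osm_p, cfg$global_raster), p)
  }

  if ("validate" %in% stages) {
    osm_p <- need(file.path(cfg$out_dir, "lulc_osm.asc"), "build")
    osm_r <- read_raster(osm_p)
    glob <- read_raster(cfg$global_raster)
    grid <- grid_spec(c(osm_r$xmin, osm_r$ymax - nrow(osm_r$values) * osm_r$cell,
                        osm_r$xmin + ncol(osm_r$values) * osm_r$cell,
                        osm_r$ymax), osm_r$cell, osm_r$crs)
    reclassed <- reclass_global(align_to_grid(glob, grid),
                                cfg$reclass$entries,
                                cfg$reclass$developed_codes)
    rep <- completeness(osm_r, reclassed, reg)
    message("validate: overall completeness ",
            round(rep$overall_completeness, 4))
    p <- file.path(cfg$out_dir, "completeness.json")
    jsonlite::write_json(
      list(overall_completeness = rep$overall_completeness,
           urban_proportion = rep$urban_proportion,
           unknown_subcategory_share = as.list(rep$unknown_subcategory_share),
           per_class_area_diff = as.list(rep$per_class_area_diff),
           per_class_ratio = as.list(rep$per_class_ratio)),
      p, auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(
      data.frame(class = names(rep$per_class_area_diff),
                 area_diff_m2 = as.numeric(rep$per_class_area_diff),
                 coverage_ratio = as.numeric(rep$per_class_ratio)),
      file.path(cfg$out_dir, "completeness_by_class.csv"), row.names = FALSE)
    artifacts$validate <- p
    write_manifest(cfg, "validate", osm_p, p)
  }

  if ("index" %in% stages) {
    lulc_p <- need(file.path(cfg$out_dir, "lulc.asc"), "integrate")
    lulc <- read_raster(lulc_p)
    idx <- urbanization_index(lulc, cfg$index_cfg)
    p <- file.path(cfg$out_dir, "index.asc")
    write_raster(idx, p)
    artifacts$index <- p
    write_manifest(cfg, "index", lulc_p, p)
  }

  if ("occupancy" %in% stages) {
    idx_p <- need(file.path(cfg$out_dir, "index.asc"), "index")
    if (is.null(cfg$detections) || is.null(cfg$sites)) {
      um_stop("occupancy stage needs detections and sites CSV paths")
    }
    idx <- read_raster(idx_p)
    det <- utils::read.csv(cfg$detections)
    sites <- utils::read.csv(cfg$sites)
    h <- build_detection_history(det, sites)
    cov <- summarize_covariate(idx, h$sites)
    fit_null <- fit_autologistic(h, formula = "null", seed = cfg$seed)
    fit_cov <- fit_autologistic(h, cov, formula = "covariate",
                                seed = cfg$seed)
    tab <- compare_aic(list(null = fit_null, urbanization = fit_cov))
    nv <- naive_occupancy(h)
    p <- file.path(cfg$out_dir, "occupancy.json")
    jsonlite::write_json(list(
      naive_occupancy = list(per_season = as.list(nv$per_season),
                             average = nv$average),
      fits = list(
        null = list(coef = as.list(fit_null$coef), logLik = fit_null$logLik,
                    K = fit_null$K, AIC = fit_null$AIC,
                    converged = fit_null$converged),
        urbanization = list(coef = as.list(fit_cov$coef),
                            se = as.list(fit_cov$se),
                            logLik = fit_cov$logLik, K = fit_cov$K,
                            AIC = fit_cov$AIC,
                            converged = fit_cov$converged)),
      aic_table = tab), p, auto_unbox = TRUE, digits = NA, null = "null")
    txt <- utils::capture.output(print(tab, row.names = FALSE))
    writeLines(txt, file.path(cfg$out_dir, "occupancy_table.txt"))
    artifacts$occupancy <- p
    write_manifest(cfg, "occupancy", c(idx_p, cfg$detections, cfg$sites), p)
  }

  invisible(artifacts)
}
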