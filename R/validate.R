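#' Completeness of the detailed (pre-backfill) raster
#'
#' Quantifies how much of the study area the tag-derived raster actually
#' covers before the global backfill: the fraction of non-void cells, the
#' absolute per-class area difference against the global raster, the area
#' share of the unknown-subcategory classes (7 protected-green, 17
#' road-unknown, 28 developed-unknown), and the urban proportion of the
#' global picture. Per-class coverage is additionally reported as the
#' normalized ratio `min(1, area_detail / area_global)` for cross-city
#' comparability.
#'
#' @param osm_r merged detail [cat_raster()] (nodata = void).
#' @param global_r reclassified global [cat_raster()] on the same grid.
#' @param reg a [class_registry()].
#' @return A list of class `completeness_report` with fields
#'   `overall_completeness`, `per_class_area_diff`, `per_class_ratio`,
#'   `unknown_subcategory_share`, `urban_proportion`.
#' @export
completeness <- function(osm_r, global_r, reg) {
  check_same_grid(osm_r, global_r)
  total <- length(osm_r$values)
  void <- sum(osm_r$values == osm_r$nodata)
  codes <- sort(union(unique(osm_r$values[osm_r$values != osm_r$nodata]),
                      unique(global_r$values[global_r$values != global_r$nodata])))
  a_osm <- class_areas(osm_r, codes)
  a_glo <- class_areas(global_r, codes)
  ratio <- ifelse(a_glo > 0, pmin(1, a_osm / a_glo), NA_real_)
  cell_area <- osm_r$cell^2
  unk <- vapply(c(7L, 17L, 28L), function(cd) {
    sum(osm_r$values == cd) * cell_area
  }, 0) / (total * cell_area)
  structure(list(
    overall_completeness = 1 - void / total,
    per_class_area_diff = abs(a_osm - a_glo),
    per_class_ratio = ratio,
    unknown_subcategory_share = stats::setNames(unk, c("7", "17", "28")),
    urban_proportion = urban_proportion(global_r, reg)
  ), class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat("<completeness_report>\n",
      "  overall completeness: ", round(x$overall_completeness, 4), "\n",
      "  urban proportion:     ", round(x$urban_proportion, 4), "\n",
      "  unknown shares (7/17/28): ",
      paste(round(x$unknown_subcategory_share, 4), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' Urban proportion of a classified raster
#'
#' Fraction of the study area covered by land-use and infrastructure classes
#' (including developed-unknown), i.e. developed surface over total surface.
#'
#' @param r a framework-legend [cat_raster()].
#' @param reg a [class_registry()].
#' @return A fraction in `[0, 1]`.
#' @export
urban_proportion <- function(r, reg) {
  stopifnot(inherits(r, "cat_raster"))
  sum(r$values %in% urban_codes(reg)) / length(r$values)
}

#' Stratified random sample of cells
#'
#' Samples up to `n_per_class` cells uniformly without replacement within
#' each class present in the raster (classes with fewer cells are exhausted).
#' Reproducible under `seed`.
#'
#' @param r a [cat_raster()].
#' @param n_per_class target sample size per class (>= 1).
#' @param seed integer RNG seed.
#' @return data.frame with columns `row`, `col`, `x`, `y`, `predicted_code`.
#' @export
stratified_sample <- function(r, n_per_class, seed = 1L) {
  stopifnot(inherits(r, "cat_raster"))
  if (n_per_class < 1) um_stop("n_per_class must be >= 1")
  v <- r$values
  codes <- sort(unique(v[v != r$nodata]))
  if (!length(codes)) um_stop("raster has no classified cells to sample")
  set.seed(seed)
  out <- list()
  for (cd in codes) {
    cells <- which(v == cd)
    take <- if (length(cells) <= n_per_class) cells
            else sample(cells, n_per_class)
    out[[as.character(cd)]] <- data.frame(cell = take, predicted_code = cd)
  }
  df <- do.call(rbind, out)
  row <- (df$cell - 1L) %% nrow(v) + 1L
  col <- (df$cell - 1L) %/% nrow(v) + 1L
  data.frame(
    row = row, col = col,
    x = r$xmin + (col - 0.5) * r$cell,
    y = r$ymax - (row - 0.5) * r$cell,
    predicted_code = df$predicted_code,
    row.names = NULL
  )
}

#' Confusion matrix from predicted/reference pairs
#'
#' Rows are the predicted class, columns the reference class (the orientation
#' under which the row-normalized diagonal is per-class precision).
#'
#' @param predicted,reference vectors of class codes.
#' @param labels label set; defaults to the sorted union of both vectors.
#' @return An integer matrix of class `confusion_matrix` with dimnames
#'   `predicted` x `reference`.
#' @export
confusion <- function(predicted, reference, labels = NULL) {
  if (length(predicted) != length(reference)) {
    um_stop("predicted and reference must have equal length")
  }
  if (is.null(labels)) labels <- sort(unique(c(predicted, reference)))
  bad <- setdiff(unique(c(predicted, reference)), labels)
  if (length(bad)) {
    um_stop("code(s) outside the declared label set: ",
            paste(bad, collapse = ", "))
  }
  p <- factor(predicted, levels = labels)
  q <- factor(reference, levels = labels)
  m <- table(predicted = p, reference = q)
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(predicted = as.character(labels),
                              reference = as.character(labels)))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = trace / N` and expected agreement
#' `p_e = sum_i row_i * col_i / N^2`. The degenerate single-class case
#' (`p_o = p_e = 1`) returns 1.
#'
#' @param cm a [confusion()] matrix (or any square count matrix).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_statistic <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  if (n == 0) um_stop("confusion matrix has no observations")
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe == 1) {
    if (po == 1) return(1)
    um_stop("expected agreement is 1 but observed is not; degenerate matrix")
  }
  (po - pe) / (1 - pe)
}

#' Per-class precision
#'
#' `precision_c = TP_c / (TP_c + FP_c)`, the row-normalized diagonal: among
#' cells predicted as class c, the fraction whose reference is c. Classes
#' never predicted get `NA`, not 0.
#'
#' @param cm a [confusion()] matrix.
#' @return Named numeric vector, one entry per class.
#' @export
precision_by_class <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) um_stop("confusion matrix has no observations")
  rs <- rowSums(cm)
  out <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  stats::setNames(out, rownames(cm))
}

#' Paired-area linear regression
#'
#' Ordinary least squares of reference areas on comparison-layer areas,
#' `y = a + b x`, with the coefficient of determination — the procedure used
#' to compare per-layer building surface areas across cities.
#'
#' @param x comparison-layer areas (one value per city/region).
#' @param y reference areas, same length (>= 3).
#' @return List with `slope`, `intercept`, `r_squared` and the `lm` fit.
#' @export
area_regression <- function(x, y) {
  if (length(x) != length(y)) um_stop("x and y must have equal length")
  if (length(x) < 3) um_stop("need at least 3 paired areas")
  if (stats::var(x) == 0) um_stop("zero variance in x; regression undefined")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::var(y) == 0) 0 else
    suppressWarnings(summary(fit)$r.squared)  # lm warns on perfect fits
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    fit = fit
  )
}
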