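# Delta-method downscaling: per-model monthly anomalies relative to a
# 1995-2014 modeled baseline, regridded to the observed climatology grid
# with nearest-cell fill, added to the observed climatology, and refined
# onto the fine depth-masked projection grid.

#' Monthly climatological baseline of a temperature series
#'
#' Per-cell, per-month-of-year mean over the baseline years, producing 12
#' climatological layers per variable.
#'
#' @param series temperature series (list with `grid`, `time`, `sst`,
#'   `sbt`)
#' @param years baseline years (default 1995--2014); all must be covered
#' @return object of class `climatology`: list with `grid`, `years`, and
#'   `sst`, `sbt` matrices (cells x 12 months)
#' @export
model_baseline <- function(series, years = 1995:2014) {
  missing_years <- setdiff(years, unique(series$time$year))
  if (length(missing_years))
    stop("model_baseline: series does not cover years ",
         paste(head(missing_years, 5), collapse = ", "))
  sel <- series$time$year %in% years
  month <- series$time$month[sel]
  sst <- sapply(1:12, function(m) rowMeans(series$sst[, sel, drop = FALSE][, month == m, drop = FALSE]))
  sbt <- sapply(1:12, function(m) rowMeans(series$sbt[, sel, drop = FALSE][, month == m, drop = FALSE]))
  structure(list(grid = series$grid, years = years, sst = sst, sbt = sbt),
            class = "climatology")
}

#' Monthly anomalies of a series relative to its own baseline
#'
#' delta(cell, year, month) = series(cell, year, month) -
#' baseline(cell, month).  By construction the anomalies average to zero
#' over the baseline period for every cell and month of year, which is
#' what removes the model's mean bias in the delta method.
#'
#' @param series temperature series on the baseline's grid
#' @param baseline a `climatology` from [model_baseline()]
#' @return delta series: list with `grid`, `time`, `sst`, `sbt`
#' @export
compute_delta <- function(series, baseline) {
  if (nrow(series$grid) != nrow(baseline$grid) ||
      any(series$grid$lat != baseline$grid$lat) ||
      any(series$grid$lon != baseline$grid$lon))
    stop("compute_delta: series and baseline grids do not match")
  m <- series$time$month
  structure(list(grid = series$grid, time = series$time,
                 sst = series$sst - baseline$sst[, m, drop = FALSE],
                 sbt = series$sbt - baseline$sbt[, m, drop = FALSE]),
            class = "delta_series")
}

#' Nearest-cell mapping between two grids
#'
#' For each target cell, finds the nearest (great-circle) native cell
#' among those carrying data.  Target cells that do not fall inside any
#' native cell's footprint are "filled" from outside the native domain;
#' their fraction is reported, mirroring how climate-model output with
#' restricted coverage is extended over an observational grid.
#'
#' @param native_grid grid data frame with `lat`, `lon` (+ step
#'   attributes)
#' @param target_grid grid data frame with `lat`, `lon`
#' @param valid logical vector marking native cells that carry data
#'   (default: all)
#' @return list: `index` (row of `native_grid` for each target cell) and
#'   `filled_fraction`
#' @export
regrid_nearest <- function(native_grid, target_grid, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, nrow(native_grid))
  cand <- which(valid)
  if (length(cand) == 0) stop("regrid_nearest: empty native domain")
  step_lat <- attr(native_grid, "step_lat")
  step_lon <- attr(native_grid, "step_lon")
  if (is.null(step_lat)) stop("regrid_nearest: native grid lacks step attributes")
  nlat <- native_grid$lat[cand]
  nlon <- native_grid$lon[cand]
  index <- integer(nrow(target_grid))
  inside <- logical(nrow(target_grid))
  for (i in seq_len(nrow(target_grid))) {
    d <- .haversine_many(target_grid$lat[i], target_grid$lon[i], nlat, nlon)
    j <- which.min(d)
    index[i] <- cand[j]
    inside[i] <- abs(target_grid$lat[i] - nlat[j]) <= step_lat / 2 + 1e-9 &&
      abs(target_grid$lon[i] - nlon[j]) <= step_lon / 2 + 1e-9
  }
  list(index = index, filled_fraction = mean(!inside))
}

#' Apply anomalies to an observed climatology
#'
#' projected(cell, year, month) = climatology(cell, month) +
#' delta(cell, year, month).  A zero anomaly therefore reproduces the
#' observed climatology exactly, and all interannual variability of the
#' projected series comes from the climate model's anomalies.
#'
#' @param climatology observed `climatology` (12 monthly layers)
#' @param delta delta series on the same grid (e.g. [compute_delta()]
#'   output regridded with [regrid_nearest()])
#' @return projected temperature series: list with `grid`, `time`,
#'   `sst`, `sbt`
#' @export
apply_delta <- function(climatology, delta) {
  if (nrow(climatology$grid) != nrow(delta$grid) ||
      any(climatology$grid$lat != delta$grid$lat) ||
      any(climatology$grid$lon != delta$grid$lon))
    stop("apply_delta: climatology and delta grids do not match")
  m <- delta$time$month
  structure(list(grid = climatology$grid, time = delta$time,
                 sst = climatology$sst[, m, drop = FALSE] + delta$sst,
                 sbt = climatology$sbt[, m, drop = FALSE] + delta$sbt),
            class = "temp_series")
}

#' Build the fine projection grid
#'
#' Retains cells of a fine bathymetry grid that are ocean and strictly
#' shallower than the depth cutoff, attaches the static rugosity and
#' grain-size layers, and labels each cell's analysis region: cells west
#' of the split longitude are the Gulf-of-Mexico side, the rest the
#' Atlantic side.
#'
#' @param fine_grid grid data frame with `lat`, `lon`, `depth` (+ step
#'   attributes)
#' @param rugosity,grain_phi per-cell static layers (same order)
#' @param depth_cutoff depth limit in m (cells with `depth < cutoff`
#'   retained; default 401)
#' @param gulf_split_lon split longitude (default -80.75)
#' @return projection-grid data frame: `cell` (new index), `src_cell`
#'   (row in `fine_grid`), `lat`, `lon`, `depth`, `rugosity`,
#'   `grain_phi`, `region`; step attributes preserved
#' @export
build_projection_grid <- function(fine_grid, rugosity, grain_phi,
                                  depth_cutoff = 401,
                                  gulf_split_lon = -80.75) {
  keep <- which(!is.na(fine_grid$depth) & fine_grid$depth < depth_cutoff)
  out <- data.frame(cell = seq_along(keep), src_cell = keep,
                    lat = fine_grid$lat[keep], lon = fine_grid$lon[keep],
                    depth = fine_grid$depth[keep],
                    rugosity = rugosity[keep],
                    grain_phi = grain_phi[keep],
                    region = ifelse(fine_grid$lon[keep] < gulf_split_lon,
                                    "gulf_of_mexico", "atlantic"))
  attr(out, "step_lat") <- attr(fine_grid, "step_lat")
  attr(out, "step_lon") <- attr(fine_grid, "step_lon")
  out
}
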