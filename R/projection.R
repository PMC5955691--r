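# Driving the fitted niche model over the projection grid and the
# downscaled temperature series: one summer biomass field per year,
# aggregated into twenty-year bins.

#' Twenty-year aggregation bins for the 2007--2100 projections
#' (the first bin spans the 14 present-day years 2007--2020)
#' @export
PROJECTION_BINS <- list("2007-2020" = 2007:2020,
                        "2021-2040" = 2021:2040,
                        "2041-2060" = 2041:2060,
                        "2061-2080" = 2061:2080,
                        "2081-2100" = 2081:2100)

#' Summer predictor fields for one projection year
#'
#' Per-cell seasonal means over the July--September summer window and
#' bottom/surface extremes over the twelve months ending in September of
#' `year`, combined with the grid's static rugosity and grain-size layers
#' and a reference survey level.
#'
#' @param series projected temperature series on the projection grid
#' @param grid projection grid ([build_projection_grid()]); its `cell`
#'   rows must correspond to the series grid rows
#' @param year projection year
#' @return predictor data frame (one row per grid cell)
#' @export
summer_predictors <- function(series, grid, year) {
  ti <- .t_idx(series, rep(year, 3), 7:9)
  if (ti[1] < 12)
    stop("summer_predictors: series lacks the 12 months preceding summer")
  win <- (ti[3] - 11):ti[3]              # Oct (year-1) .. Sep (year)
  sst_cols <- lapply(win, function(j) series$sst[, j])
  sbt_cols <- lapply(win, function(j) series$sbt[, j])
  data.frame(
    sst_seasonal = (series$sst[, ti[1]] + series$sst[, ti[2]] +
                      series$sst[, ti[3]]) / 3,
    sbt_seasonal = (series$sbt[, ti[1]] + series$sbt[, ti[2]] +
                      series$sbt[, ti[3]]) / 3,
    sbt_min = Reduce(pmin, sbt_cols),
    sbt_max = Reduce(pmax, sbt_cols),
    sst_max = Reduce(pmax, sst_cols),
    rugosity = grid$rugosity,
    grain_phi = grid$grain_phi)
}

#' Project one species' summer biomass field for one year
#'
#' Assembles [summer_predictors()] for the year and evaluates
#' [predict_biomass()] at every projection-grid cell (reference survey
#' level).
#'
#' @param model a `two_stage_model`
#' @param grid projection grid
#' @param series projected temperature series on the projection grid
#' @param year projection year
#' @param interpolate use the fast additive-interpolation predictor
#'   (see [predict_biomass()]); default `TRUE` for grid-scale work
#' @return numeric vector of biomass densities (one per grid cell)
#' @export
project_species <- function(model, grid, series, year, interpolate = TRUE) {
  predict_biomass(model, summer_predictors(series, grid, year),
                  interpolate = interpolate)
}

#' Project a species over a span of years
#'
#' Stacks the per-year predictor frames and evaluates the model once,
#' returning the annual summer biomass fields as a cells x years matrix.
#'
#' @inheritParams project_species
#' @param years projection years (default 2007--2100)
#' @param interpolate use the fast additive-interpolation predictor
#' @return matrix (cells x years, columns named by year)
#' @export
project_years <- function(model, grid, series, years = 2007:2100,
                          interpolate = TRUE) {
  preds <- do.call(rbind, lapply(years, summer_predictors,
                                 series = series, grid = grid))
  bio <- predict_biomass(model, preds, interpolate = interpolate)
  matrix(bio, nrow = nrow(grid), ncol = length(years),
         dimnames = list(NULL, years))
}

#' Average annual fields into twenty-year bins
#'
#' @param fields matrix of annual fields (cells x years, columns named by
#'   year) or a numeric vector of annual scalars named by year
#' @param bins named list of bin years (default [PROJECTION_BINS])
#' @return matrix (cells x bins) or named vector of bin means
#' @export
bin_series <- function(fields, bins = PROJECTION_BINS) {
  vec <- is.null(dim(fields))
  if (vec) fields <- matrix(fields, nrow = 1,
                            dimnames = list(NULL, names(fields)))
  years <- as.integer(colnames(fields))
  missing_years <- setdiff(unlist(bins), years)
  if (length(missing_years))
    stop("bin_series: fields lack years ",
         paste(head(missing_years, 5), collapse = ", "))
  out <- vapply(bins, function(ys)
    rowMeans(fields[, as.character(ys), drop = FALSE]),
    numeric(nrow(fields)))
  if (is.null(dim(out))) {               # single-cell input
    if (vec) return(out)
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(bins)))
  }
  out
}
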