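# Construction of the seven environmental predictors: 3-month seasonal
# surface/bottom temperature means, 12-month temperature extremes,
# seafloor rugosity, and sediment grain size (Phi) interpolated by
# inverse distance weighting.

# Column index of (year, month) in a temperature series' time table.
.t_idx <- function(series, year, month) {
  idx <- match(year * 12L + month, series$time$year * 12L + series$time$month)
  if (any(is.na(idx)))
    stop("temperature series does not cover the requested year/month")
  idx
}

#' Three-month seasonal temperature means at a cell
#'
#' Mean surface and bottom temperature over the month of the haul and the
#' preceding and following months (crossing year boundaries as needed).
#'
#' @param series a temperature series (e.g. a `shelf_world` or the output
#'   of [apply_delta()]): list with `time`, `sst`, `sbt`
#' @param cell cell index (row of the series grid)
#' @param year,month centre of the window
#' @return named numeric `c(sst_seasonal = , sbt_seasonal = )`
#' @export
seasonal_mean <- function(series, cell, year, month) {
  if (length(cell) != 1 || cell < 1 || cell > nrow(series$sst))
    stop("seasonal_mean: invalid cell index")
  ti <- .t_idx(series, year, month)
  if (ti == 1 || ti == nrow(series$time))
    stop("seasonal_mean: window extends outside the series")
  cols <- (ti - 1):(ti + 1)
  c(sst_seasonal = mean(series$sst[cell, cols]),
    sbt_seasonal = mean(series$sbt[cell, cols]))
}

#' Annual temperature extremes preceding a haul
#'
#' Minimum and maximum bottom temperature and maximum surface temperature
#' over the twelve-month window ending at (and including) the haul month.
#'
#' @inheritParams seasonal_mean
#' @return named numeric `c(sbt_min = , sbt_max = , sst_max = )`
#' @export
annual_extremes <- function(series, cell, year, month) {
  if (length(cell) != 1 || cell < 1 || cell > nrow(series$sst))
    stop("annual_extremes: invalid cell index")
  ti <- .t_idx(series, year, month)
  if (ti < 12) stop("annual_extremes: 12-month window extends before series start")
  cols <- (ti - 11):ti
  c(sbt_min = min(series$sbt[cell, cols]),
    sbt_max = max(series$sbt[cell, cols]),
    sst_max = max(series$sst[cell, cols]))
}

#' Reshape values on a lat-major grid into a latitude x longitude matrix
#' @param grid grid data frame with `nlat`/`nlon` attributes
#' @param values per-cell values in grid row order
#' @return matrix with `nlat` rows and `nlon` columns
#' @export
grid_to_matrix <- function(grid, values) {
  nlat <- attr(grid, "nlat"); nlon <- attr(grid, "nlon")
  if (is.null(nlat) || is.null(nlon))
    stop("grid_to_matrix: grid lacks nlat/nlon attributes")
  matrix(values, nrow = nlat, ncol = nlon, byrow = TRUE)
}

#' @rdname grid_to_matrix
#' @param mat matrix as produced by [grid_to_matrix()]
#' @export
matrix_to_grid <- function(mat) as.vector(t(mat))

#' Seafloor rugosity from a bathymetry grid
#'
#' Rugosity of a cell is the mean absolute difference between its depth
#' and the depths of its eight surrounding cells.  Edge cells use the
#' neighbours that exist; missing (land) neighbours are ignored.  A cell
#' that is itself missing, or whose whole neighbourhood is missing,
#' returns `NA`.
#'
#' @param depth matrix of depths (rows = latitudes, columns = longitudes),
#'   `NA` for land
#' @return matrix of rugosity values (same shape, >= 0)
#' @export
compute_rugosity <- function(depth) {
  if (!is.matrix(depth)) stop("compute_rugosity: depth must be a matrix")
  nr <- nrow(depth); nc <- ncol(depth)
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  pad <- matrix(NA_real_, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- depth
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj), drop = FALSE]
    d <- abs(depth - nb)
    ok <- !is.na(d)
    acc[ok] <- acc[ok] + d[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  out <- acc / cnt          # cnt 0 -> NaN
  out[cnt == 0L] <- NA_real_
  out[is.na(depth)] <- NA_real_
  out
}

#' Block-average a fine grid onto a coarser grid
#'
#' Averages `factor` x `factor` blocks of a matrix, ignoring missing
#' cells; an all-missing block stays missing.  The matrix dimensions must
#' be integer multiples of `factor`.
#'
#' @param mat fine-resolution matrix
#' @param factor integer aggregation factor (coarse step / fine step)
#' @return matrix with dimensions `dim(mat) / factor`
#' @export
aggregate_grid <- function(mat, factor) {
  if (!is.matrix(mat)) stop("aggregate_grid: mat must be a matrix")
  if (factor != round(factor) || factor < 1)
    stop("aggregate_grid: factor must be a positive integer")
  factor <- as.integer(factor)
  if (nrow(mat) %% factor != 0 || ncol(mat) %% factor != 0)
    stop("aggregate_grid: matrix dimensions must be multiples of factor")
  nr <- nrow(mat) %/% factor
  nc <- ncol(mat) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    for (j in seq_len(nc)) {
      cols <- ((j - 1) * factor + 1):(j * factor)
      block <- mat[rows, cols]
      if (all(is.na(block))) next
      out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

#' Sediment grain size (Phi) from gravel/sand/mud percentages
#'
#' Fraction-weighted mean of the pure-sediment-type Phi anchors: gravel
#' -2.7, sand 1.7, mud 7.5.  Lower Phi is coarser sediment.
#'
#' @param gravel,sand,mud percentages (each >= 0, summing to 100 within
#'   +/- 1); vectorized
#' @param phi_pure anchors for the pure types, overridable
#' @return Phi values in \[-2.7, 7.5\] (for the default anchors)
#' @examples
#' gsm_to_phi(0, 0, 100)    # 7.5 (pure mud)
#' gsm_to_phi(100, 0, 0)    # -2.7 (pure gravel)
#' @export
gsm_to_phi <- function(gravel, sand, mud,
                       phi_pure = c(gravel = -2.7, sand = 1.7, mud = 7.5)) {
  if (any(c(gravel, sand, mud) < 0))
    stop("gsm_to_phi: percentages must be non-negative")
  total <- gravel + sand + mud
  if (any(abs(total - 100) > 1))
    stop("gsm_to_phi: gravel + sand + mud must equal 100 (+/- 1)")
  (gravel * phi_pure[["gravel"]] + sand * phi_pure[["sand"]] +
     mud * phi_pure[["mud"]]) / total
}

# Vectorized haversine distance (km) from one point to many.
.haversine_many <- function(lat0, lon0, lat, lon) {
  phi0 <- deg2rad(lat0); phi <- deg2rad(lat)
  dphi <- phi - phi0
  dlam <- deg2rad(lon - lon0)
  h <- sin(dphi / 2)^2 + cos(phi0) * cos(phi) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(sqrt(pmin(pmax(h, 0), 1)))
}

#' Inverse-distance-weighted interpolation
#'
#' Interpolates point values onto target locations with weights
#' proportional to great-circle distance to the power `-power`.  A target
#' coincident with a data point returns that point's value exactly (the
#' limit of the weight formula); outputs are convex combinations of the
#' inputs and so bounded by their range.
#'
#' @param points data frame with `lat`, `lon` and a value column
#' @param targets data frame with `lat`, `lon`
#' @param value name of the value column in `points`
#' @param power positive distance exponent (default 2)
#' @return numeric vector of interpolated values, one per target row
#' @export
idw_interpolate <- function(points, targets, value = "value", power = 2) {
  if (nrow(points) == 0) stop("idw_interpolate: empty point set")
  if (!value %in% names(points))
    stop("idw_interpolate: no column '", value, "' in points")
  v <- points[[value]]
  vapply(seq_len(nrow(targets)), function(i) {
    d <- .haversine_many(targets$lat[i], targets$lon[i],
                         points$lat, points$lon)
    hit <- d < 1e-9
    if (any(hit)) return(mean(v[hit]))
    w <- d^(-power)
    sum(w * v) / sum(w)
  }, numeric(1))
}

#' Assemble the seven model predictors for a haul table
#'
#' For every haul, computes the 3-month seasonal surface and bottom
#' temperature means centred on the haul month, the minimum/maximum
#' bottom and maximum surface temperature over the preceding 12 months,
#' and attaches static rugosity and grain-size layers plus the survey
#' factor.
#'
#' @param series temperature series covering every haul's window (e.g. a
#'   `shelf_world`)
#' @param hauls haul table with `cell`, `year`, `month`, `survey_id`
#' @param rugosity,grain_phi per-cell static layers on the series grid
#'   (`NULL` fills 0, for worlds without those layers)
#' @return data frame with `haul_id` and columns `sst_seasonal`,
#'   `sbt_seasonal`, `sbt_min`, `sbt_max`, `sst_max`, `rugosity`,
#'   `grain_phi`, `survey_id`
#' @export
haul_predictors <- function(series, hauls, rugosity = NULL,
                            grain_phi = NULL) {
  ti <- .t_idx(series, hauls$year, hauls$month)
  if (any(ti < 12) || any(ti >= nrow(series$time)))
    stop("haul_predictors: some hauls fall outside the usable series window")
  cell <- hauls$cell
  sst3 <- (series$sst[cbind(cell, ti - 1)] + series$sst[cbind(cell, ti)] +
             series$sst[cbind(cell, ti + 1)]) / 3
  sbt3 <- (series$sbt[cbind(cell, ti - 1)] + series$sbt[cbind(cell, ti)] +
             series$sbt[cbind(cell, ti + 1)]) / 3
  sbt_min <- sbt_max <- series$sbt[cbind(cell, ti)]
  sst_max <- series$sst[cbind(cell, ti)]
  for (k in 1:11) {
    sb <- series$sbt[cbind(cell, ti - k)]
    ss <- series$sst[cbind(cell, ti - k)]
    sbt_min <- pmin(sbt_min, sb)
    sbt_max <- pmax(sbt_max, sb)
    sst_max <- pmax(sst_max, ss)
  }
  data.frame(haul_id = hauls$haul_id,
             sst_seasonal = sst3, sbt_seasonal = sbt3,
             sbt_min = sbt_min, sbt_max = sbt_max, sst_max = sst_max,
             rugosity = if (is.null(rugosity)) 0 else rugosity[cell],
             grain_phi = if (is.null(grain_phi)) 0 else grain_phi[cell],
             survey_id = hauls$survey_id)
}
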