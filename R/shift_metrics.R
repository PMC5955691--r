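# Centroid-shift geometry: spherical geodesy, area weighting, habitat totals.

#' Mean Earth radius (km) used by all spherical formulas
#' @keywords internal
EARTH_RADIUS_KM <- 6371

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Area of an equal-angle grid cell
#'
#' Area in km^2 of a `step_lat` x `step_lon` (degrees) cell centred at
#' latitude `lat` on a sphere of radius 6371 km.  Cell areas shrink with
#' the cosine of latitude as meridians converge; this weighting enters all
#' biomass centroid and habitat-total calculations.
#'
#' @param lat cell-centre latitude, degrees; must satisfy |lat| < 90
#' @param step_lat,step_lon cell size in degrees (longitude step defaults
#'   to the latitude step)
#' @return area in km^2 (vectorized over `lat`)
#' @examples
#' cell_area(0, 0.05)          # ~30.9 km^2 at the equator
#' cell_area(60, 1) / cell_area(0, 1)  # = cos(60 deg) = 0.5
#' @export
cell_area <- function(lat, step_lat, step_lon = step_lat) {
  if (any(!is.finite(lat)) || any(abs(lat) >= 90))
    stop("cell_area: latitude must be finite and strictly inside (-90, 90)")
  if (step_lat <= 0 || step_lon <= 0)
    stop("cell_area: grid steps must be positive")
  arc <- EARTH_RADIUS_KM * pi / 180
  (arc * step_lat) * (arc * step_lon) * cos(deg2rad(lat))
}

#' Great-circle distance and initial bearing
#'
#' Haversine distance (km, sphere radius 6371 km) and initial bearing
#' (degrees clockwise from north, in \[0, 360)) from point `a` to point
#' `b`.  Coincident points return distance 0 and, by convention, bearing 0.
#'
#' @param a,b numeric length-2 vectors `c(lat, lon)` in degrees
#' @return named numeric vector `c(distance_km = , bearing_deg = )`
#' @examples
#' great_circle(c(0, 0), c(0, 1))   # ~111.19 km due east (bearing 90)
#' @export
great_circle <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  if (any(abs(c(a[1], b[1])) > 90))
    stop("great_circle: |latitude| must not exceed 90")
  phi1 <- deg2rad(a[[1]]); lam1 <- deg2rad(a[[2]])
  phi2 <- deg2rad(b[[1]]); lam2 <- deg2rad(b[[2]])
  dphi <- phi2 - phi1
  dlam <- lam2 - lam1
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  h <- min(max(h, 0), 1)
  dist <- 2 * EARTH_RADIUS_KM * asin(sqrt(h))
  if (dist == 0) {
    bearing <- 0
  } else {
    y <- sin(dlam) * cos(phi2)
    x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
    bearing <- rad2deg(atan2(y, x)) %% 360
  }
  c(distance_km = dist, bearing_deg = bearing)
}

#' Biomass-weighted centroid of a density field
#'
#' Weighted mean latitude and longitude of a biomass-density field on a
#' grid, with weights density x cell area (so poleward cells, which cover
#' less area per degree, contribute less).  Longitudes are averaged in a
#' continuous frame anchored at the weighted field's westernmost occupied
#' cell, so grids straddling the antimeridian (e.g. Aleutian-type domains)
#' average correctly; the result is mapped back to (-180, 180].
#'
#' The centroid is not confined to the grid: it may fall over land or
#' water deeper than the projection mask.
#'
#' @param density non-negative density per cell (same order as `grid` rows)
#' @param grid data frame with `lat`, `lon` columns; cell steps are read
#'   from attributes `step_lat`/`step_lon` or passed explicitly
#' @param region optional logical/index vector restricting the calculation
#'   (e.g. Gulf of Mexico cells only)
#' @param step_lat,step_lon cell size in degrees, overriding grid attributes
#' @return named numeric `c(lat = , lon = )`; both `NA` (with a warning)
#'   when the total weighted biomass is zero
#' @export
biomass_centroid <- function(density, grid, region = NULL,
                             step_lat = NULL, step_lon = NULL) {
  if (length(density) != nrow(grid))
    stop("biomass_centroid: density length must match grid rows")
  if (any(density < 0, na.rm = TRUE))
    stop("biomass_centroid: density must be non-negative")
  if (is.null(step_lat)) step_lat <- attr(grid, "step_lat")
  if (is.null(step_lon)) step_lon <- attr(grid, "step_lon")
  if (is.null(step_lat)) stop("biomass_centroid: grid step unknown")
  if (is.null(step_lon)) step_lon <- step_lat
  if (!is.null(region)) {
    grid <- grid[region, , drop = FALSE]
    density <- density[region]
  }
  keep <- is.finite(density) & density > 0
  w <- density[keep] * cell_area(grid$lat[keep], step_lat, step_lon)
  if (length(w) == 0 || sum(w) <= 0) {
    warning("biomass_centroid: zero total biomass; centroid undefined")
    return(c(lat = NA_real_, lon = NA_real_))
  }
  lat_c <- sum(w * grid$lat[keep]) / sum(w)
  # continuous longitude frame: anchor just past the largest circular
  # gap between occupied longitudes, so domains straddling the
  # antimeridian average correctly
  ls <- sort(unique(grid$lon[keep]))
  gaps <- diff(c(ls, ls[1] + 360))
  lon0 <- if (length(ls) > 1) ls[which.max(gaps) %% length(ls) + 1] else ls[1]
  lon_shift <- (grid$lon[keep] - lon0) %% 360
  lon_c <- lon0 + sum(w * lon_shift) / sum(w)
  lon_c <- ((lon_c + 180) %% 360) - 180
  if (lon_c == -180) lon_c <- 180
  c(lat = lat_c, lon = lon_c)
}

#' Centroid shift between two time periods
#'
#' Great-circle displacement between a start-period and end-period
#' biomass centroid: distance (km), initial bearing (degrees from north)
#' and the signed change in latitude.
#'
#' @param start,end centroids as `c(lat, lon)` (from [biomass_centroid()])
#' @return data frame with `lat0`, `lon0`, `lat1`, `lon1`, `distance_km`,
#'   `bearing_deg`, `dlat`
#' @export
centroid_shift <- function(start, end) {
  gc <- great_circle(start, end)
  data.frame(lat0 = start[[1]], lon0 = start[[2]],
             lat1 = end[[1]], lon1 = end[[2]],
             distance_km = gc[["distance_km"]],
             bearing_deg = gc[["bearing_deg"]],
             dlat = end[[1]] - start[[1]])
}

#' Total thermal habitat per bin and percent change
#'
#' Total habitat in a time bin is the sum over grid cells of biomass
#' density times cell area.  Change is expressed as a percentage of the
#' first (present-day) bin's total.
#'
#' @param bin_fields matrix of density fields, cells x bins (columns named
#'   by bin label), or a single numeric vector for one bin
#' @param grid projection grid data frame with `lat` (and step attributes)
#' @param region optional logical/index filter on cells
#' @param step_lat,step_lon cell size in degrees, overriding grid attributes
#' @return list with `totals` (named per bin) and `pct_change` (percent,
#'   end bin vs first bin; `NA` with a warning when the first-bin total is
#'   zero, as can happen for species entering a region late in the century)
#' @export
habitat_change <- function(bin_fields, grid, region = NULL,
                           step_lat = NULL, step_lon = NULL) {
  if (is.null(dim(bin_fields))) bin_fields <- cbind(bin = bin_fields)
  if (nrow(bin_fields) != nrow(grid))
    stop("habitat_change: field rows must match grid rows")
  if (is.null(step_lat)) step_lat <- attr(grid, "step_lat")
  if (is.null(step_lon)) step_lon <- attr(grid, "step_lon")
  if (is.null(step_lat)) stop("habitat_change: grid step unknown")
  if (is.null(step_lon)) step_lon <- step_lat
  if (!is.null(region)) {
    grid <- grid[region, , drop = FALSE]
    bin_fields <- bin_fields[region, , drop = FALSE]
  }
  area <- cell_area(grid$lat, step_lat, step_lon)
  totals <- colSums(bin_fields * area, na.rm = TRUE)
  if (totals[1] <= 0) {
    warning("habitat_change: zero habitat in the first bin; pct_change undefined")
    pct <- NA_real_
  } else {
    pct <- unname(100 * (totals[length(totals)] - totals[1]) / totals[1])
  }
  list(totals = totals, pct_change = pct)
}

#' Ensemble summary of per-GCM centroid shifts
#'
#' Sample mean and standard deviation (n - 1 denominator) across climate
#' models of shift distance and latitudinal change, plus the circular
#' directional-agreement statistic of the shift bearings.
#'
#' @param shifts data frame with one row per GCM and columns
#'   `distance_km`, `bearing_deg`, `dlat` (as built by [centroid_shift()])
#' @return one-row data frame: `n_gcm`, `mean_dist`, `sd_dist`,
#'   `mean_dlat`, `sd_dlat`, `agreement_R`
#' @export
ensemble_stats <- function(shifts) {
  if (nrow(shifts) < 2)
    stop("ensemble_stats: at least two GCM shifts required")
  data.frame(
    n_gcm = nrow(shifts),
    mean_dist = mean(shifts$distance_km),
    sd_dist = sd(shifts$distance_km),
    mean_dlat = mean(shifts$dlat),
    sd_dlat = sd(shifts$dlat),
    agreement_R = directional_agreement(shifts$bearing_deg)
  )
}
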