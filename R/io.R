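# Plain-text exchange formats: gridded fields and monthly temperature
# series as long-format CSV (lat, lon, time, value columns), the
# dependency-light equivalent of the usual gridded formats.

#' Write a gridded field table as long-format CSV
#'
#' @param grid grid data frame with `lat`, `lon`
#' @param values named list or data frame of per-cell value columns
#' @param path output path
#' @export
write_field_csv <- function(grid, values, path) {
  df <- data.frame(lat = grid$lat, lon = grid$lon, as.data.frame(values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a monthly temperature series as long-format CSV
#'
#' One row per (cell, year, month) with `lat`, `lon`, `year`, `month`,
#' `sst`, `sbt`.  [read_series_csv()] reconstructs the series object,
#' including the regular-grid attributes, so the pair round-trips.
#'
#' @param series temperature series (list with `grid`, `time`, `sst`,
#'   `sbt`)
#' @param path output path
#' @export
write_series_csv <- function(series, path) {
  nt <- nrow(series$time)
  nc <- nrow(series$grid)
  df <- data.frame(
    lat = rep(series$grid$lat, nt),
    lon = rep(series$grid$lon, nt),
    year = rep(series$time$year, each = nc),
    month = rep(series$time$month, each = nc),
    sst = as.vector(series$sst),
    sbt = as.vector(series$sbt))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @return `read_series_csv()`: the reconstructed series
#' @export
read_series_csv <- function(path) {
  df <- read.csv(path)
  lats <- sort(unique(df$lat))
  lons <- sort(unique(df$lon))
  g <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  grid <- data.frame(cell = seq_len(nrow(g)), lat = g$lat, lon = g$lon)
  attr(grid, "nlat") <- length(lats)
  attr(grid, "nlon") <- length(lons)
  attr(grid, "step_lat") <- if (length(lats) > 1) stats::median(diff(lats)) else NA_real_
  attr(grid, "step_lon") <- if (length(lons) > 1) stats::median(diff(lons)) else NA_real_
  tkey <- df$year * 12L + df$month
  tu <- sort(unique(tkey))
  time <- data.frame(year = tu %/% 12L, month = tu %% 12L)
  time$year[time$month == 0] <- time$year[time$month == 0] - 1L
  time$month[time$month == 0] <- 12L
  ci <- (match(df$lat, lats) - 1L) * length(lons) + match(df$lon, lons)
  ti <- match(tkey, tu)
  sst <- matrix(NA_real_, nrow(grid), length(tu))
  sbt <- matrix(NA_real_, nrow(grid), length(tu))
  sst[cbind(ci, ti)] <- df$sst
  sbt[cbind(ci, ti)] <- df$sbt
  structure(list(grid = grid, time = time, sst = sst, sbt = sbt),
            class = "temp_series")
}
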