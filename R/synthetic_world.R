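# Synthetic world: a shelf grid with bathymetry, a seasonally varying,
# poleward-cooling temperature climatology, an ensemble of warming
# trajectories under two emission scenarios, sediment samples, and
# multi-survey trawl sampling of species with known Gaussian thermal
# niches.  Everything is deterministic under the configured seed, so the
# whole projection pipeline can be exercised and validated against known
# ground truth without any external data.

#' Configuration for a synthetic shelf world
#'
#' Collects the constants that define a synthetic study domain.  Defaults
#' mirror the fixed choices of the projection pipeline: a 1995--2014
#' climatological baseline, projections 2007--2100, a 16-model climate
#' ensemble under a strong-mitigation and a business-as-usual scenario, a
#' 401 m depth cutoff, and a Gulf-of-Mexico/Atlantic split longitude of
#' -80.75 degrees.
#'
#' @param lat_range,lon_range numeric length-2, domain extent in degrees
#'   (longitude negative west)
#' @param climate_step grid step (degrees) of the coarse climate/
#'   climatology grid
#' @param proj_step grid step (degrees) of the fine projection grid
#' @param hist_years years covered by the historical temperature series
#' @param baseline_years climatological baseline years
#' @param proj_years years covered by projections
#' @param n_gcms number of climate models in the ensemble (>= 2)
#' @param scenarios character labels, low scenario first
#' @param depth_cutoff projections restricted to depths shallower than
#'   this (m); the boundary value itself is excluded
#' @param gulf_split_lon longitude separating the Gulf-of-Mexico side from
#'   the Atlantic side of a grid
#' @param seed integer seed driving all randomness derived from this world
#' @return object of class `world_config` (a named list)
#' @export
world_config <- function(lat_range = c(25, 55),
                         lon_range = c(-76, -64),
                         climate_step = 0.5,
                         proj_step = 0.05,
                         hist_years = 1980:2014,
                         baseline_years = 1995:2014,
                         proj_years = 2007:2100,
                         n_gcms = 16,
                         scenarios = c("rcp26", "rcp85"),
                         depth_cutoff = 401,
                         gulf_split_lon = -80.75,
                         seed = 1L) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2,
            diff(lat_range) > 0, diff(lon_range) > 0)
  if (climate_step <= 0 || proj_step <= 0)
    stop("world_config: grid steps must be positive")
  if (length(hist_years) == 0 || length(proj_years) == 0)
    stop("world_config: year ranges must be non-empty")
  if (n_gcms < 2) stop("world_config: n_gcms must be at least 2")
  if (length(scenarios) != 2)
    stop("world_config: exactly two scenario labels expected")
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 climate_step = climate_step, proj_step = proj_step,
                 hist_years = hist_years, baseline_years = baseline_years,
                 proj_years = proj_years, n_gcms = n_gcms,
                 scenarios = scenarios, depth_cutoff = depth_cutoff,
                 gulf_split_lon = gulf_split_lon, seed = as.integer(seed)),
            class = "world_config")
}

# Regular cell-centre grid over an extent (inclusive endpoints).
# Rows are ordered latitude-major (all longitudes of the first latitude,
# then the next latitude), matching the row-flattening used by the
# matrix-based field operations.
make_grid <- function(lat_range, lon_range, step) {
  lats <- seq(lat_range[1], lat_range[2], by = step)
  lons <- seq(lon_range[1], lon_range[2], by = step)
  if (length(lats) * length(lons) < 2)
    stop("make_grid: degenerate single-cell grid")
  g <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  g <- data.frame(cell = seq_len(nrow(g)), lat = g$lat, lon = g$lon)
  attr(g, "nlat") <- length(lats)
  attr(g, "nlon") <- length(lons)
  attr(g, "step_lat") <- step
  attr(g, "step_lon") <- step
  g
}

# Deterministic synthetic bathymetry (m, positive down; NA = land).
# A coastal land strip sits along the western edge; depth increases
# offshore past the projection depth cutoff, with smooth undulations that
# give the rugosity operator something to measure.
synthetic_depth <- function(lat, lon, config) {
  frac <- (lon - config$lon_range[1]) / diff(config$lon_range)
  depth <- -40 + 700 * frac^1.4 +
    25 * sin(lat * 0.9) * cos(lon * 1.3) +
    15 * sin(3 * lat + 2 * lon)
  depth[depth <= 0] <- NA_real_
  depth
}

# Deterministic climatological temperature components (deg C).
# Surface temperature declines poleward and peaks in August; bottom
# temperature is the surface mean minus a depth-dependent offset, with a
# damped seasonal cycle.
clim_sst <- function(lat, month) {
  28 - 0.45 * (lat - 20) + 4 * cos(2 * pi * (month - 8) / 12)
}
clim_sbt <- function(lat, month, depth) {
  28 - 0.45 * (lat - 20) - 6 * depth / (depth + 200) +
    1.5 * cos(2 * pi * (month - 8) / 12)
}

#' Generate a synthetic shelf world
#'
#' Builds the coarse climate grid with synthetic bathymetry and monthly
#' surface/bottom temperature fields over the configured historical years.
#' Temperatures combine a poleward-cooling mean state, a seasonal cycle
#' peaking in late summer, a depth-dependent surface-to-bottom offset, and
#' interannual Gaussian noise.  Land cells carry `NA` temperatures.
#'
#' @param config a [world_config()]
#' @param noise_sd interannual temperature noise SD (deg C)
#' @return object of class `shelf_world`: list with `config`, `grid`
#'   (climate grid with `depth`), `time` (year/month index), and `sst`,
#'   `sbt` matrices (cells x months)
#' @export
make_world <- function(config, noise_sd = 0.3) {
  stopifnot(inherits(config, "world_config"))
  grid <- make_grid(config$lat_range, config$lon_range, config$climate_step)
  grid$depth <- synthetic_depth(grid$lat, grid$lon, config)
  time <- expand.grid(month = 1:12, year = config$hist_years,
                      KEEP.OUT.ATTRS = FALSE)[, c("year", "month")]
  set.seed(config$seed)
  nt <- nrow(time)
  nc <- nrow(grid)
  sst <- outer(grid$lat, time$month, clim_sst) +
    matrix(rnorm(nc * nt, sd = noise_sd), nc, nt)
  sbt <- matrix(clim_sbt(rep(grid$lat, nt), rep(time$month, each = nc),
                         rep(grid$depth, nt)), nc, nt) +
    matrix(rnorm(nc * nt, sd = noise_sd), nc, nt)
  land <- is.na(grid$depth)
  sst[land, ] <- NA_real_
  sbt[land, ] <- NA_real_
  structure(list(config = config, grid = grid, time = time,
                 sst = sst, sbt = sbt),
            class = "shelf_world")
}

#' Specification of one synthetic climate model
#'
#' @param gcm_id label
#' @param amplitude named numeric, end-of-century warming (deg C, mean of
#'   2081--2100 minus mean of 1995--2014) per scenario; the high scenario
#'   must warm at least as much as the low one
#' @param pattern_coef dimensionless latitudinal modulation of the warming
#'   (positive = poleward-amplified)
#' @param noise_sd interannual noise SD (deg C)
#' @param coverage fraction (0, 1] of the domain's latitude span covered
#'   by the model's native grid; the remainder must be filled from the
#'   nearest in-domain cell during regridding
#' @param bias constant offset (deg C) of the model's climatology relative
#'   to the observed one (removed by the delta method)
#' @return object of class `gcm_spec`
#' @export
gcm_spec <- function(gcm_id, amplitude, pattern_coef = 0,
                     noise_sd = 0.1, coverage = 1, bias = 0) {
  stopifnot(length(amplitude) == 2)
  if (is.null(names(amplitude))) names(amplitude) <- c("low", "high")
  if (amplitude[2] < amplitude[1])
    stop("gcm_spec: high-scenario amplitude must be >= low-scenario amplitude")
  if (noise_sd < 0) stop("gcm_spec: noise_sd must be >= 0")
  if (coverage <= 0 || coverage > 1)
    stop("gcm_spec: coverage must be in (0, 1]")
  structure(list(gcm_id = gcm_id, amplitude = amplitude,
                 pattern_coef = pattern_coef, noise_sd = noise_sd,
                 coverage = coverage, bias = bias),
            class = "gcm_spec")
}

#' Default synthetic climate-model ensemble specifications
#'
#' A spread of warming amplitudes (roughly 0.5--1.5 deg C under the low
#' scenario and 2--4.5 deg C under the high one, matching the canonical
#' scenario spread), alternating poleward amplification, and a few models
#' with restricted native domains so nearest-cell fill is exercised.
#'
#' @param n number of models
#' @return list of [gcm_spec()] objects
#' @export
default_gcm_specs <- function(n = 16) {
  lapply(seq_len(n), function(i) {
    f <- (i - 1) / max(n - 1, 1)
    gcm_spec(gcm_id = sprintf("gcm%02d", i),
             amplitude = c(low = 0.5 + 1 * f, high = 2 + 2.5 * f),
             pattern_coef = 0.3 * (-1)^i,
             noise_sd = 0.1,
             coverage = if (i %% 5 == 0) 0.7 else 1,
             bias = (-1)^i * 0.5 * f)
  })
}

# Warming time profile: 0 on average over 1995-2014 and 1 on average over
# 2081-2100 (linear ramp between the two window midpoints).
warming_ramp <- function(year) (year - 2004.5) / (2090.5 - 2004.5)

#' Generate a synthetic climate-model ensemble
#'
#' Produces monthly surface/bottom temperature series for each model and
#' scenario on each model's native grid (twice the climate-grid step,
#' optionally trimmed to a fraction of the latitude span).  Each series is
#' the deterministic climatology plus the model's constant bias, its
#' scenario warming amplitude times a linear ramp (zero-mean over
#' 1995--2014, unit-mean over 2081--2100) modulated by a latitudinal
#' pattern, plus interannual noise.
#'
#' @param world a `shelf_world`
#' @param specs list of [gcm_spec()]; defaults to
#'   `default_gcm_specs(config$n_gcms)`
#' @param years years of the generated series (default baseline start
#'   through projection end, e.g. 1995--2100)
#' @return object of class `gcm_ensemble`: list with `time` and `gcms`,
#'   each model a list with `spec`, `grid`, and per-scenario `fields`
#'   (`sst`, `sbt` matrices)
#' @export
make_gcm_ensemble <- function(world, specs = NULL, years = NULL) {
  stopifnot(inherits(world, "shelf_world"))
  config <- world$config
  if (is.null(specs)) specs <- default_gcm_specs(config$n_gcms)
  if (length(specs) != config$n_gcms)
    stop("make_gcm_ensemble: specs length must equal n_gcms")
  if (is.null(years))
    years <- min(config$baseline_years):max(config$proj_years)
  time <- expand.grid(month = 1:12, year = years,
                      KEEP.OUT.ATTRS = FALSE)[, c("year", "month")]
  nt <- nrow(time)
  mid_lat <- mean(config$lat_range)
  half_span <- diff(config$lat_range) / 2
  set.seed(config$seed + 1L)
  gcms <- lapply(specs, function(sp) {
    lat_top <- config$lat_range[1] + sp$coverage * diff(config$lat_range)
    grid <- make_grid(c(config$lat_range[1], lat_top), config$lon_range,
                      2 * config$climate_step)
    grid$depth <- synthetic_depth(grid$lat, grid$lon, config)
    nc <- nrow(grid)
    pattern <- 1 + sp$pattern_coef * (grid$lat - mid_lat) / half_span
    ramp <- warming_ramp(time$year)
    fields <- lapply(setNames(seq_along(config$scenarios), config$scenarios),
                     function(si) {
      amp <- sp$amplitude[si]
      warm <- outer(pattern, ramp) * amp
      sst <- outer(grid$lat, time$month, clim_sst) + sp$bias + warm +
        matrix(rnorm(nc * nt, sd = sp$noise_sd), nc, nt)
      sbt <- matrix(clim_sbt(rep(grid$lat, nt), rep(time$month, each = nc),
                             rep(grid$depth, nt)), nc, nt) + sp$bias + warm +
        matrix(rnorm(nc * nt, sd = sp$noise_sd), nc, nt)
      land <- is.na(grid$depth)
      sst[land, ] <- NA_real_
      sbt[land, ] <- NA_real_
      list(sst = sst, sbt = sbt)
    })
    list(spec = sp, grid = grid, fields = fields)
  })
  names(gcms) <- vapply(specs, function(s) s$gcm_id, character(1))
  structure(list(time = time, gcms = gcms, scenarios = config$scenarios),
            class = "gcm_ensemble")
}

#' Ground-truth description of a synthetic species
#'
#' Occurrence follows a Gaussian thermal-suitability curve centred on the
#' bottom-temperature optimum: suitability
#' \eqn{S = \exp(-(SBT - T_{opt})^2 / (2\,\sigma^2))}, occurrence
#' probability \eqn{p = \min(1, prevalence \times S)}, and positive catch
#' densities are lognormal around `max_density * S * catchability`.
#'
#' @param species_id label
#' @param t_opt bottom-temperature optimum (deg C)
#' @param niche_sd thermal niche breadth (deg C, > 0)
#' @param max_density biomass density at the optimum (> 0)
#' @param prevalence occurrence probability scalar at the optimum, (0, 1]
#' @param ext_min,ext_max per-deg-C log-linear sensitivities to the annual
#'   minimum/maximum bottom temperature (default 0)
#' @param rug_coef,phi_coef log-linear rugosity and grain-size preference
#'   coefficients (default 0)
#' @param sdlog lognormal catch-density scatter on the log scale
#' @return object of class `species_truth`
#' @export
species_truth <- function(species_id, t_opt, niche_sd = 2,
                          max_density = 50, prevalence = 0.8,
                          ext_min = 0, ext_max = 0,
                          rug_coef = 0, phi_coef = 0, sdlog = 0.6) {
  if (niche_sd <= 0) stop("species_truth: niche_sd must be > 0")
  if (max_density <= 0) stop("species_truth: max_density must be > 0")
  if (prevalence <= 0 || prevalence > 1)
    stop("species_truth: prevalence must be in (0, 1]")
  structure(list(species_id = species_id, t_opt = t_opt,
                 niche_sd = niche_sd, max_density = max_density,
                 prevalence = prevalence, ext_min = ext_min,
                 ext_max = ext_max, rug_coef = rug_coef,
                 phi_coef = phi_coef, sdlog = sdlog),
            class = "species_truth")
}

#' Specification of one synthetic trawl survey
#'
#' @param survey_id label
#' @param region region label
#' @param coast coast label (`"atlantic"`, `"pacific"` or
#'   `"gulf_of_mexico"`)
#' @param lat_range latitude band sampled by the survey
#' @param months season months sampled (1--12)
#' @param years years the survey is active
#' @param hauls_per_year number of hauls per active year
#' @param catchability survey catchability multiplier (>= 0; 0 means the
#'   gear never retains the species, so no catches are recorded)
#' @param swept_meanlog,swept_sdlog lognormal swept-area parameters
#' @return object of class `survey_spec`
#' @export
survey_spec <- function(survey_id, region, coast = "atlantic",
                        lat_range, months = 7:9, years = 1990:2014,
                        hauls_per_year = 100, catchability = 1,
                        swept_meanlog = log(0.02), swept_sdlog = 0.2) {
  if (catchability < 0) stop("survey_spec: catchability must be >= 0")
  if (!all(months %in% 1:12)) stop("survey_spec: months must be in 1..12")
  structure(list(survey_id = survey_id, region = region, coast = coast,
                 lat_range = lat_range, months = months, years = years,
                 hauls_per_year = hauls_per_year,
                 catchability = catchability,
                 swept_meanlog = swept_meanlog, swept_sdlog = swept_sdlog),
            class = "survey_spec")
}

# Gaussian thermal suitability in (0, 1].
thermal_suitability <- function(sbt, truth) {
  exp(-(sbt - truth$t_opt)^2 / (2 * truth$niche_sd^2))
}

# Full suitability including optional extreme/static-habitat preferences,
# given a predictor data frame with sbt_seasonal, sbt_min, sbt_max,
# rugosity, grain_phi columns (missing columns treated as absent terms).
truth_suitability <- function(pred, truth) {
  s <- thermal_suitability(pred$sbt_seasonal, truth)
  lin <- 0
  if (truth$ext_min != 0) lin <- lin + truth$ext_min * pred$sbt_min
  if (truth$ext_max != 0) lin <- lin + truth$ext_max * pred$sbt_max
  if (truth$rug_coef != 0) lin <- lin + truth$rug_coef * pred$rugosity
  if (truth$phi_coef != 0) lin <- lin + truth$phi_coef * pred$grain_phi
  s * exp(lin)
}

#' Occurrence probability implied by a species truth
#'
#' Analytic occurrence probability used by the survey simulator:
#' `min(1, prevalence * suitability)`.  Exposed so empirical frequencies
#' from repeated simulation can be checked against the generating model.
#'
#' @param pred data frame of predictors (needs `sbt_seasonal`; optional
#'   `sbt_min`, `sbt_max`, `rugosity`, `grain_phi`)
#' @param truth a [species_truth()]
#' @return probability vector in \[0, 1\]
#' @export
occurrence_probability <- function(pred, truth) {
  pmin(1, truth$prevalence * truth_suitability(pred, truth))
}

#' Simulate multi-survey trawl sampling of synthetic species
#'
#' Draws haul locations and dates for each survey, computes each species'
#' thermal suitability from the world's bottom temperatures (3-month
#' seasonal mean centred on the haul month), and samples occurrence and
#' lognormal positive catch weights.  The catch table contains positive
#' catches only, matching real survey exports in which absences are
#' implicit.
#'
#' @param world a `shelf_world`
#' @param species list of [species_truth()] (non-empty)
#' @param surveys list of [survey_spec()] covering at least two regions
#' @param seed integer seed (default derived from the world seed)
#' @return list with `hauls` (haul_id, survey_id, region, coast, year,
#'   month, day, lat, lon, depth, swept_area) and `catch` (haul_id,
#'   species_id, weight)
#' @export
simulate_surveys <- function(world, species, surveys,
                             seed = world$config$seed + 2L) {
  stopifnot(inherits(world, "shelf_world"))
  if (length(species) == 0) stop("simulate_surveys: species list is empty")
  if (length(unique(vapply(surveys, function(s) s$region, character(1)))) < 2)
    stop("simulate_surveys: surveys must cover at least two regions")
  config <- world$config
  set.seed(seed)
  step <- config$climate_step
  hauls_list <- list()
  for (sv in surveys) {
    yrs <- intersect(sv$years, config$hist_years)
    ok <- !is.na(world$grid$depth) & world$grid$depth < config$depth_cutoff &
      world$grid$lat >= sv$lat_range[1] & world$grid$lat <= sv$lat_range[2]
    cells <- world$grid$cell[ok]
    if (length(cells) == 0)
      stop("simulate_surveys: survey ", sv$survey_id, " has no sampleable cells")
    n <- length(yrs) * sv$hauls_per_year
    cell <- sample(cells, n, replace = TRUE)
    hauls_list[[sv$survey_id]] <- data.frame(
      survey_id = sv$survey_id, region = sv$region, coast = sv$coast,
      year = rep(yrs, each = sv$hauls_per_year),
      month = sample(sv$months, n, replace = TRUE),
      day = sample(1:28, n, replace = TRUE),
      cell = cell,
      lat = world$grid$lat[cell] + runif(n, -step / 2, step / 2),
      lon = world$grid$lon[cell] + runif(n, -step / 2, step / 2),
      depth = world$grid$depth[cell],
      swept_area = rlnorm(n, sv$swept_meanlog, sv$swept_sdlog))
  }
  hauls <- do.call(rbind, hauls_list)
  rownames(hauls) <- NULL
  hauls$haul_id <- sprintf("%s-%05d", hauls$survey_id,
                           stats::ave(seq_len(nrow(hauls)), hauls$survey_id,
                                      FUN = seq_along))
  # seasonal bottom temperature (haul month +/- 1) drives the truth
  ti <- .t_idx(world, hauls$year, hauls$month)
  sbt_seas <- (world$sbt[cbind(hauls$cell, ti - 1)] +
                 world$sbt[cbind(hauls$cell, ti)] +
                 world$sbt[cbind(hauls$cell, ti + 1)]) / 3
  q <- setNames(vapply(surveys, function(s) s$catchability, numeric(1)),
                vapply(surveys, function(s) s$survey_id, character(1)))
  catch_list <- list()
  for (sp in species) {
    s <- thermal_suitability(sbt_seas, sp)
    p <- pmin(1, sp$prevalence * s)
    occ <- rbinom(nrow(hauls), 1, p) == 1
    qh <- q[hauls$survey_id]
    pos <- occ & qh > 0
    if (!any(pos)) next
    dens <- rlnorm(sum(pos),
                   meanlog = log(sp$max_density * s[pos] * qh[pos]),
                   sdlog = sp$sdlog)
    catch_list[[sp$species_id]] <- data.frame(
      haul_id = hauls$haul_id[pos], species_id = sp$species_id,
      weight = dens * hauls$swept_area[pos])
  }
  catch <- if (length(catch_list)) do.call(rbind, catch_list) else
    data.frame(haul_id = character(), species_id = character(),
               weight = numeric())
  rownames(catch) <- NULL
  hauls <- hauls[, c("haul_id", "survey_id", "region", "coast", "year",
                     "month", "day", "cell", "lat", "lon", "depth",
                     "swept_area")]
  list(hauls = hauls, catch = catch)
}

#' Simulate sediment point samples
#'
#' Draws point samples of %gravel/%sand/%mud composition over the ocean
#' cells of a world: mud fraction increases with depth, gravel decreases,
#' with Dirichlet-like noise.  Used to exercise the grain-size conversion
#' and inverse-distance interpolation.
#'
#' @param world a `shelf_world`
#' @param n number of points
#' @param seed integer seed
#' @return data frame with `lat`, `lon`, `gravel`, `sand`, `mud`
#'   (percentages summing to 100)
#' @export
simulate_sediment <- function(world, n = 200, seed = world$config$seed + 3L) {
  set.seed(seed)
  ok <- which(!is.na(world$grid$depth))
  cell <- sample(ok, n, replace = TRUE)
  depth <- world$grid$depth[cell]
  f <- depth / (depth + 150)           # deeper -> muddier
  alpha <- cbind(gravel = 2 * (1 - f), sand = 3, mud = 1 + 4 * f)
  draw <- matrix(rgamma(3 * n, shape = as.vector(alpha)), n, 3)
  comp <- 100 * draw / rowSums(draw)
  step <- world$config$climate_step
  data.frame(lat = world$grid$lat[cell] + runif(n, -step / 2, step / 2),
             lon = world$grid$lon[cell] + runif(n, -step / 2, step / 2),
             gravel = comp[, 1], sand = comp[, 2], mud = comp[, 3])
}

#' Simulate an ensemble shift-statistics table
#'
#' Generates per-species ensemble summaries with the structure the
#' uncertainty classifiers assume: log-linear mean--SD relations with
#' lognormal scatter for both shift distance and latitudinal shift, and
#' directional-agreement values drawn independently of the distance
#' residuals.  Used for classification calibration studies.
#'
#' @param n_species number of species projections
#' @param a_dist,b_dist intercept/slope of `ln(sd_dist)` on
#'   `ln(mean_dist)`
#' @param a_lat,b_lat intercept/slope of `ln(sd_dlat)` on
#'   `ln(|mean_dlat|)`
#' @param noise_sd SD of the lognormal scatter around each relation
#' @param seed integer seed
#' @return data frame with `species_id`, `mean_dist`, `sd_dist`,
#'   `agreement_R`, `mean_dlat`, `sd_dlat`
#' @export
simulate_shift_table <- function(n_species = 878,
                                 a_dist = -0.7, b_dist = 1,
                                 a_lat = -0.9, b_lat = 1,
                                 noise_sd = 0.6, seed = 1L) {
  set.seed(seed)
  mean_dist <- rlnorm(n_species, meanlog = 4.5, sdlog = 1.1)
  sd_dist <- exp(a_dist + b_dist * log(mean_dist) +
                   rnorm(n_species, sd = noise_sd))
  agreement <- rbeta(n_species, 2, 1.2)
  mean_dlat <- (-1)^rbinom(n_species, 1, 0.2) *
    rlnorm(n_species, meanlog = 0, sdlog = 1)
  sd_dlat <- exp(a_lat + b_lat * log(abs(mean_dlat)) +
                   rnorm(n_species, sd = noise_sd))
  data.frame(species_id = sprintf("sp%04d", seq_len(n_species)),
             mean_dist = mean_dist, sd_dist = sd_dist,
             agreement_R = agreement,
             mean_dlat = mean_dlat, sd_dlat = sd_dlat)
}
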