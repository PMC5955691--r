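test_that("grid construction gives the expected cell count", {
  cfg <- world_config(lat_range = c(20, 60), lon_range = c(0, 10),
                      climate_step = 1, n_gcms = 2, seed = 1)
  w <- make_world(cfg)
  expect_equal(nrow(w$grid), 41 * 11)
  expect_equal(attr(w$grid, "nlat"), 41)
  expect_equal(attr(w$grid, "nlon"), 11)
})

test_that("degenerate single-cell grids are rejected", {
  expect_error(thermshift:::make_grid(c(30, 30), c(-70, -70), 1),
               "degenerate")
})

test_that("world generation is deterministic under the seed", {
  cfg <- tiny_config(seed = 99)
  w1 <- make_world(cfg)
  w2 <- make_world(cfg)
  expect_identical(w1$sst, w2$sst)
  expect_identical(w1$sbt, w2$sbt)
})

test_that("surface temperature declines poleward in July", {
  cfg <- world_config(lat_range = c(20, 60), lon_range = c(0, 10),
                      climate_step = 1, n_gcms = 2, seed = 2)
  w <- make_world(cfg)
  july <- w$time$month == 7
  s25 <- mean(w$sst[w$grid$lat == 25, july], na.rm = TRUE)
  s55 <- mean(w$sst[w$grid$lat == 55, july], na.rm = TRUE)
  expect_gt(s25, s55)
  # and matches the generator's own gradient: 0.45 deg C per deg lat
  expect_equal(s25 - s55, 0.45 * 30, tolerance = 0.05)
})

test_that("bottom temperature is cooler than surface over deep cells", {
  w <- tiny_world()
  deep <- which(!is.na(w$grid$depth) & w$grid$depth > 100)
  expect_true(mean(w$sst[deep, ] - w$sbt[deep, ], na.rm = TRUE) > 0)
})

test_that("GCM ensemble recovers configured warming amplitudes", {
  w <- tiny_world()
  specs <- list(
    gcm_spec("flat", amplitude = c(low = 0, high = 0), noise_sd = 0),
    gcm_spec("warm3", amplitude = c(low = 3, high = 3), noise_sd = 0))
  ens <- make_gcm_ensemble(w, specs)
  base <- ens$time$year %in% 1995:2014
  endc <- ens$time$year %in% 2081:2100
  for (gid in c("flat", "warm3")) {
    f <- ens$gcms[[gid]]$fields$rcp85$sbt
    d <- mean(f[, endc], na.rm = TRUE) - mean(f[, base], na.rm = TRUE)
    expect_equal(d, if (gid == "flat") 0 else 3, tolerance = 1e-10)
  }
  # zero-amplitude, zero-noise model is flat: every year equals baseline
  flat <- ens$gcms$flat$fields$rcp26$sst
  ocean <- !is.na(ens$gcms$flat$grid$depth)
  jan <- which(ens$time$month == 1)
  expect_equal(flat[ocean, jan[1]], flat[ocean, jan[length(jan)]],
               tolerance = 1e-12)
})

test_that("high scenario warms at least as much as low, per model", {
  w <- tiny_world()
  ens <- make_gcm_ensemble(w)
  base <- ens$time$year %in% 1995:2014
  endc <- ens$time$year %in% 2081:2100
  for (g in ens$gcms) {
    d_low <- mean(g$fields$rcp26$sbt[, endc], na.rm = TRUE) -
      mean(g$fields$rcp26$sbt[, base], na.rm = TRUE)
    d_high <- mean(g$fields$rcp85$sbt[, endc], na.rm = TRUE) -
      mean(g$fields$rcp85$sbt[, base], na.rm = TRUE)
    expect_gte(d_high, d_low)
    # configured amplitude recovered within 3 standard errors of the noise
    se <- g$spec$noise_sd / sqrt(sum(base))
    expect_lt(abs(d_high - g$spec$amplitude[["high"]]), 3 * se + 1e-6)
  }
})

test_that("distinct amplitudes give distinct delta fields", {
  cfg <- tiny_config()
  cfg$n_gcms <- 4L
  w <- make_world(cfg)
  specs <- lapply(1:4, function(i)
    gcm_spec(paste0("g", i), amplitude = c(low = i / 2, high = i),
             noise_sd = 0))
  ens <- make_gcm_ensemble(w, specs)
  base <- ens$time$year %in% 1995:2014
  endc <- ens$time$year %in% 2081:2100
  deltas <- vapply(ens$gcms, function(g)
    mean(g$fields$rcp85$sst[, endc], na.rm = TRUE) -
      mean(g$fields$rcp85$sst[, base], na.rm = TRUE), numeric(1))
  expect_equal(length(unique(round(deltas, 6))), 4)
})

test_that("survey simulation is deterministic and respects catchability", {
  w <- tiny_world()
  species <- list(species_truth("sp1", t_opt = 18))
  surveys <- list(
    survey_spec("dead", region = "south", coast = "atlantic",
                lat_range = c(30, 35), years = 2000:2010,
                hauls_per_year = 50, catchability = 0),
    survey_spec("live", region = "north", coast = "atlantic",
                lat_range = c(35, 40), years = 2000:2010,
                hauls_per_year = 50, catchability = 1))
  s1 <- simulate_surveys(w, species, surveys, seed = 7)
  s2 <- simulate_surveys(w, species, surveys, seed = 7)
  expect_identical(s1$hauls, s2$hauls)
  expect_identical(s1$catch, s2$catch)
  dead_hauls <- s1$hauls$haul_id[s1$hauls$survey_id == "dead"]
  expect_false(any(s1$catch$haul_id %in% dead_hauls))
  expect_error(simulate_surveys(w, list(), surveys), "empty")
})

test_that("occurrence peaks in the latitude band holding the optimum", {
  cfg <- world_config(lat_range = c(25, 55), lon_range = c(-75, -70),
                      climate_step = 0.5, n_gcms = 2, seed = 5)
  w <- make_world(cfg)
  # optimum = seasonal bottom temperature at 40N mid-domain summer
  ok <- which(!is.na(w$grid$depth) & abs(w$grid$lat - 40) < 0.3)
  sel <- w$time$month == 8
  t40 <- mean(w$sbt[ok, sel], na.rm = TRUE)
  species <- list(species_truth("target", t_opt = t40, niche_sd = 1.2,
                                prevalence = 0.9))
  surveys <- list(
    survey_spec("s1", region = "r1", coast = "atlantic",
                lat_range = c(25, 40), years = 2000:2009,
                hauls_per_year = 150),
    survey_spec("s2", region = "r2", coast = "atlantic",
                lat_range = c(40, 55), years = 2000:2009,
                hauls_per_year = 150))
  sim <- simulate_surveys(w, species, surveys, seed = 21)
  expect_gt(nrow(sim$hauls), 2000)
  pres <- sim$hauls$haul_id %in% sim$catch$haul_id
  band <- cut(sim$hauls$lat, breaks = seq(25, 55, by = 5))
  rate <- tapply(pres, band, mean)
  expect_equal(names(which.max(rate)), "(35,40]")
})

test_that("empirical occurrence matches the analytic probability", {
  s <- tiny_sim()
  truth <- s$species[[1]]
  p <- occurrence_probability(s$predictors, truth)
  osp <- s$obs[s$obs$species_id == "coolfish", , drop = FALSE]
  pres <- osp$present[match(s$hauls$haul_id, osp$haul_id)]
  dec <- cut(p, breaks = quantile(p, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (lv in levels(dec)) {
    idx <- which(dec == lv)
    se <- sqrt(mean(p[idx]) * (1 - mean(p[idx])) / length(idx))
    expect_lt(abs(mean(pres[idx]) - mean(p[idx])), 4 * se + 1e-3)
  }
})

test_that("sediment samples are valid compositions", {
  sed <- simulate_sediment(tiny_world(), n = 100)
  expect_equal(sed$gravel + sed$sand + sed$mud, rep(100, 100),
               tolerance = 1e-9)
  expect_true(all(sed$gravel >= 0 & sed$sand >= 0 & sed$mud >= 0))
})
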