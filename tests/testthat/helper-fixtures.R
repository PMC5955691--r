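# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small world: coarse climate grid, two surveys, two well-sampled species.
tiny_config <- function(seed = 11L) {
  world_config(lat_range = c(30, 40), lon_range = c(-75, -70),
               climate_step = 0.5, proj_step = 0.25,
               n_gcms = 2, seed = seed)
}

tiny_world <- function() cached("tiny_world", make_world(tiny_config()))

tiny_sim <- function() cached("tiny_sim", {
  w <- tiny_world()
  species <- list(species_truth("coolfish", t_opt = 16, niche_sd = 1.5),
                  species_truth("warmfish", t_opt = 21, niche_sd = 1.5))
  surveys <- list(
    survey_spec("svyA", region = "south", coast = "atlantic",
                lat_range = c(30, 35), years = 1995:2014,
                hauls_per_year = 100, catchability = 1),
    survey_spec("svyB", region = "north", coast = "atlantic",
                lat_range = c(35, 40), years = 1995:2014,
                hauls_per_year = 100, catchability = 2))
  sim <- simulate_surveys(w, species, surveys)
  catch <- standardize_catches(sim$catch, sim$hauls)
  obs <- expand_zeros(catch, sim$hauls)
  obs <- add_pseudoabsences(obs, sim$hauls, seed = 3L)
  hauls <- split_train_test(sim$hauls)
  predictors <- haul_predictors(w, hauls)
  list(world = w, species = species, surveys = surveys, hauls = hauls,
       catch = catch, obs = obs, predictors = predictors)
})

# One fitted two-stage model on the tiny world (cool-adapted species).
tiny_model <- function() cached("tiny_model", {
  s <- tiny_sim()
  o <- s$obs[s$obs$species_id == "coolfish", , drop = FALSE]
  train <- s$hauls$haul_id[s$hauls$train]
  fit_two_stage(o[o$haul_id %in% train, , drop = FALSE], s$predictors)
})

# Hand-built temperature series on a 2 x 2 ocean grid, 1995-2010, with
# known per-month values: sst = year + month/100 + cell, sbt = sst - 5.
toy_series <- function() cached("toy_series", {
  grid <- thermshift:::make_grid(c(30, 31), c(-70, -69), 1)
  time <- expand.grid(month = 1:12, year = 1995:2010,
                      KEEP.OUT.ATTRS = FALSE)[, c("year", "month")]
  base <- outer(seq_len(nrow(grid)), time$year + time$month / 100, "+")
  list(grid = grid, time = time, sst = base, sbt = base - 5)
})
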