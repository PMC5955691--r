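# End-to-end driver: synthetic world -> survey preparation -> niche
# models -> delta downscaling -> century projections -> shift metrics and
# uncertainty ratings, with all tabular artifacts written as CSV.

#' Compact configuration for a demonstration world
#'
#' A shelf domain small enough to run the full pipeline on one CPU in
#' minutes: a 10 x 5 degree Atlantic-type shelf, 0.5-degree climate grid,
#' 0.1-degree projection grid (a few thousand ocean cells shallower than
#' 401 m), and a four-model ensemble.
#'
#' @param seed integer seed
#' @param n_gcms ensemble size (default 4)
#' @return a [world_config()]
#' @export
demo_config <- function(seed = 1L, n_gcms = 4) {
  world_config(lat_range = c(30, 40), lon_range = c(-75, -70),
               climate_step = 0.5, proj_step = 0.1,
               n_gcms = n_gcms, seed = seed)
}

# Default species set: thermal optima spread across the world's range of
# summer bottom temperatures, so warm- and cool-edge behaviour are both
# represented.
.default_species <- function(world, n_species) {
  ok <- !is.na(world$grid$depth) &
    world$grid$depth < world$config$depth_cutoff
  sel <- world$time$month %in% 7:9
  sbt <- world$sbt[ok, sel, drop = FALSE]
  qs <- quantile(sbt, c(0.1, 0.9), na.rm = TRUE)
  t_opts <- seq(qs[1], qs[2], length.out = n_species)
  lapply(seq_len(n_species), function(i)
    species_truth(sprintf("species%02d", i), t_opt = t_opts[i],
                  niche_sd = 1.5, prevalence = 0.8))
}

.default_surveys <- function(world) {
  lr <- world$config$lat_range
  mid <- mean(lr)
  yrs <- intersect(1995:2014, world$config$hist_years)
  list(
    survey_spec("svy_south", region = "south", coast = "atlantic",
                lat_range = c(lr[1], mid), months = 7:9, years = yrs,
                hauls_per_year = 150, catchability = 1),
    survey_spec("svy_north", region = "north", coast = "atlantic",
                lat_range = c(mid, lr[2]), months = 7:9, years = yrs,
                hauls_per_year = 150, catchability = 1.5))
}

#' Run the full projection pipeline on a synthetic world
#'
#' Generates a world and climate-model ensemble, simulates multi-survey
#' trawl sampling of synthetic species, harmonizes the catch data, fits
#' and validates two-stage niche models, downscales every model/scenario
#' temperature series onto the fine projection grid by the delta method,
#' projects annual summer biomass 2007--2100 into twenty-year bins, and
#' computes centroid shifts, habitat change, ensemble statistics and
#' uncertainty ratings.  All tabular artifacts are written as CSV under
#' `out_dir`.
#'
#' @param config a [world_config()] (default [demo_config()])
#' @param species list of [species_truth()] (default: optima spread over
#'   the world's summer bottom-temperature range)
#' @param surveys list of [survey_spec()] (default: two seasonal surveys
#'   splitting the domain latitudinally, catchabilities 1 and 1.5)
#' @param n_species number of default species when `species` is `NULL`
#' @param min_occurrences occurrence gate (default 250)
#' @param auc_threshold validation gate (default 0.75)
#' @param out_dir output directory for CSV artifacts (`NULL` to skip
#'   writing)
#' @param verbose print progress messages
#' @return (invisibly) list with the world, tables, fitted models,
#'   per-projection shifts, ensemble statistics, and ratings
#' @export
run_pipeline <- function(config = demo_config(), species = NULL,
                         surveys = NULL, n_species = 20,
                         min_occurrences = 250, auc_threshold = 0.75,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  say("generating world and ensemble ...")
  world <- make_world(config)
  ens <- make_gcm_ensemble(world)
  if (is.null(species)) species <- .default_species(world, n_species)
  if (is.null(surveys)) surveys <- .default_surveys(world)

  say("simulating surveys ...")
  sim <- simulate_surveys(world, species, surveys)
  sediment <- simulate_sediment(world)
  sediment$phi <- gsm_to_phi(sediment$gravel, sediment$sand, sediment$mud)

  # static layers on the climate grid (for haul predictors)
  depth_clim <- grid_to_matrix(world$grid, world$grid$depth)
  rug_clim <- matrix_to_grid(compute_rugosity(depth_clim))
  phi_clim <- idw_interpolate(sediment, world$grid, value = "phi")

  say("harmonizing catch data ...")
  catch <- standardize_catches(sim$catch, sim$hauls)
  obs <- expand_zeros(catch, sim$hauls)
  obs <- add_pseudoabsences(obs, sim$hauls, seed = config$seed + 4L)
  hauls <- split_train_test(sim$hauls)
  keep <- gate_species(obs, hauls, min_occurrences = min_occurrences)
  say("  ", length(keep), " of ", length(species),
      " species pass the occurrence gate")
  predictors <- haul_predictors(world, hauls, rug_clim, phi_clim)

  say("fitting niche models ...")
  train_ids <- hauls$haul_id[hauls$train]
  test_ids <- hauls$haul_id[!hauls$train]
  models <- list()
  summary_rows <- list()
  for (sp in keep) {
    o <- obs[obs$species_id == sp, , drop = FALSE]
    fit <- fit_two_stage(o[o$haul_id %in% train_ids, , drop = FALSE],
                         predictors)
    val <- evaluate_auc(fit, o[o$haul_id %in% test_ids, , drop = FALSE],
                        predictors, threshold = auc_threshold)
    summary_rows[[sp]] <- data.frame(
      species_id = sp, n_presence = sum(o$present), auc = val$auc,
      dev_expl_occurrence = fit$deviance_explained[["stage1"]],
      dev_expl_biomass = fit$deviance_explained[["stage2"]],
      dropped = val$dropped)
    if (!val$dropped) models[[sp]] <- fit
  }
  model_summary <- do.call(rbind, summary_rows)
  rownames(model_summary) <- NULL
  say("  ", length(models), " species retained after validation")

  say("building projection grid ...")
  fine <- make_grid(config$lat_range, config$lon_range, config$proj_step)
  fine$depth <- synthetic_depth(fine$lat, fine$lon, config)
  rug_fine <- matrix_to_grid(compute_rugosity(grid_to_matrix(fine, fine$depth)))
  phi_fine <- idw_interpolate(sediment, fine, value = "phi")
  pg <- build_projection_grid(fine, rug_fine, phi_fine,
                              depth_cutoff = config$depth_cutoff,
                              gulf_split_lon = config$gulf_split_lon)

  clim <- model_baseline(world, config$baseline_years)
  ocean_clim <- !is.na(world$grid$depth)
  fine_map <- regrid_nearest(world$grid,
                             data.frame(lat = pg$lat, lon = pg$lon),
                             valid = ocean_clim)

  say("projecting ", length(models), " species x ", length(ens$gcms),
      " GCMs x 2 scenarios ...")
  years <- config$proj_years
  shift_rows <- list()
  habitat_rows <- list()
  for (gid in names(ens$gcms)) {
    g <- ens$gcms[[gid]]
    native_valid <- !is.na(g$grid$depth)
    gmap <- regrid_nearest(g$grid,
                           data.frame(lat = world$grid$lat,
                                      lon = world$grid$lon),
                           valid = native_valid)
    for (sc in ens$scenarios) {
      gseries <- list(grid = g$grid, time = ens$time,
                      sst = g$fields[[sc]]$sst, sbt = g$fields[[sc]]$sbt)
      gbase <- model_baseline(gseries, config$baseline_years)
      gdelta <- compute_delta(gseries, gbase)
      delta_clim <- list(grid = world$grid, time = ens$time,
                         sst = gdelta$sst[gmap$index, , drop = FALSE],
                         sbt = gdelta$sbt[gmap$index, , drop = FALSE])
      proj_clim <- apply_delta(clim, delta_clim)
      proj_fine <- list(grid = pg, time = ens$time,
                        sst = proj_clim$sst[fine_map$index, , drop = FALSE],
                        sbt = proj_clim$sbt[fine_map$index, , drop = FALSE])
      preds <- do.call(rbind, lapply(years, summer_predictors,
                                     series = proj_fine, grid = pg))
      for (sp in names(models)) {
        bio <- predict_biomass(models[[sp]], preds, interpolate = TRUE)
        fields <- matrix(bio, nrow = nrow(pg), ncol = length(years),
                         dimnames = list(NULL, years))
        bins <- bin_series(fields)
        cen0 <- biomass_centroid(bins[, 1], pg)
        cen1 <- biomass_centroid(bins[, ncol(bins)], pg)
        shift <- centroid_shift(cen0, cen1)
        hab <- habitat_change(bins, pg)
        shift_rows[[length(shift_rows) + 1L]] <- data.frame(
          species_id = sp, gcm = gid, scenario = sc, shift,
          pct_change = hab$pct_change,
          filled_fraction = gmap$filled_fraction)
        habitat_rows[[length(habitat_rows) + 1L]] <- data.frame(
          species_id = sp, gcm = gid, scenario = sc,
          bin = names(hab$totals), total = unname(hab$totals))
      }
    }
    say("  ", gid, " done")
  }
  shifts <- do.call(rbind, shift_rows)
  habitat <- do.call(rbind, habitat_rows)
  rownames(shifts) <- rownames(habitat) <- NULL

  say("ensemble statistics and uncertainty ratings ...")
  stats_rows <- list()
  for (sc in ens$scenarios) for (sp in names(models)) {
    ss <- shifts[shifts$scenario == sc & shifts$species_id == sp, ,
                 drop = FALSE]
    es <- ensemble_stats(ss)
    stats_rows[[length(stats_rows) + 1L]] <- data.frame(
      species_id = sp, scenario = sc, es,
      mean_pct_change = mean(ss$pct_change))
  }
  estats <- do.call(rbind, stats_rows)
  rownames(estats) <- NULL

  ratings <- NULL
  if (length(models) >= 10) {
    rating_rows <- lapply(ens$scenarios, function(sc) {
      tab <- estats[estats$scenario == sc, , drop = FALSE]
      ddu <- ddu_classify(tab)
      lu <- lu_classify(tab)
      data.frame(species_id = tab$species_id, scenario = sc,
                 ddu = ddu$rating, lu = lu$rating,
                 combined = combine_ratings(ddu$rating, lu$rating))
    })
    ratings <- do.call(rbind, rating_rows)
    rownames(ratings) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(hauls, file.path(out_dir, "hauls.csv"), row.names = FALSE)
    write.csv(catch, file.path(out_dir, "catch.csv"), row.names = FALSE)
    write.csv(model_summary, file.path(out_dir, "model_summary.csv"),
              row.names = FALSE)
    write.csv(shifts, file.path(out_dir, "shifts.csv"), row.names = FALSE)
    write.csv(estats, file.path(out_dir, "ensemble_stats.csv"),
              row.names = FALSE)
    write.csv(habitat, file.path(out_dir, "habitat.csv"),
              row.names = FALSE)
    if (!is.null(ratings))
      write.csv(ratings, file.path(out_dir, "ratings.csv"),
                row.names = FALSE)
    write.csv(cbind(pg), file.path(out_dir, "projection_grid.csv"),
              row.names = FALSE)
    write_field_csv(world$grid,
                    list(depth = world$grid$depth, rugosity = rug_clim,
                         grain_phi = phi_clim),
                    file.path(out_dir, "climate_grid_layers.csv"))
  }

  invisible(list(config = config, world = world, ensemble = ens,
                 hauls = hauls, catch = catch, obs = obs,
                 predictors = predictors, model_summary = model_summary,
                 models = models, projection_grid = pg,
                 shifts = shifts, habitat = habitat,
                 ensemble_stats = estats, ratings = ratings))
}
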