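make_hauls <- function(n, region = "r1", coast = "atlantic",
                       years = 2000, swept = 0.5, id_prefix = "h") {
  data.frame(haul_id = sprintf("%s%03d", id_prefix, seq_len(n)),
             survey_id = "s1", region = region, coast = coast,
             year = rep_len(years, n), month = 7, day = 1,
             swept_area = swept)
}

test_that("standardize_catches sums duplicates and converts to density", {
  hauls <- make_hauls(2)
  catch <- data.frame(haul_id = c("h001", "h001", "h002"),
                      species_id = c("sp", "sp", "sp"),
                      weight = c(2, 3, 1))
  out <- standardize_catches(catch, hauls)
  expect_equal(nrow(out), 2)
  expect_equal(out$biomass_density[out$haul_id == "h001"], (2 + 3) / 0.5)
  expect_equal(out$biomass_density[out$haul_id == "h002"], 1 / 0.5)
})

test_that("standardize_catches handles empty input and unknown hauls", {
  hauls <- make_hauls(2)
  empty <- standardize_catches(
    data.frame(haul_id = character(), species_id = character(),
               weight = numeric()), hauls)
  expect_equal(nrow(empty), 0)
  expect_error(standardize_catches(
    data.frame(haul_id = "nope", species_id = "sp", weight = 1), hauls),
    "unknown haul_id")
})

test_that("zero expansion conserves record counts per coast", {
  hauls <- rbind(make_hauls(60, coast = "atlantic"),
                 make_hauls(40, coast = "pacific", id_prefix = "p"))
  catch <- data.frame(haul_id = sprintf("h%03d", 1:40),
                      species_id = "sp", biomass_density = 1)
  obs <- expand_zeros(catch, hauls)
  expect_equal(nrow(obs), 60)                 # atlantic hauls only
  expect_equal(sum(obs$present), 40)
  expect_equal(sum(!obs$present), 20)
  expect_false(any(obs$haul_id %in% hauls$haul_id[hauls$coast == "pacific"]))
})

test_that("pseudoabsence counts follow the min rule in both regimes", {
  # coast with two regions; species observed only in r1
  hauls <- rbind(make_hauls(300, region = "r1"),
                 make_hauls(500, region = "r2", id_prefix = "g"))
  catch <- data.frame(haul_id = sprintf("h%03d", 1:40),
                      species_id = "sp", biomass_density = 1)
  obs <- expand_zeros(catch, hauls)
  # default: cap is 10% of all observation records (800) = 80, region
  # term is 10% of 500 = 50 -> 50 pseudoabsences
  pa <- add_pseudoabsences(obs, hauls, seed = 1)
  expect_equal(sum(pa$pseudoabsence), 50)
  expect_true(all(pa$haul_id[pa$pseudoabsence] %in%
                    hauls$haul_id[hauls$region == "r2"]))
  expect_true(all(pa$biomass_density[pa$pseudoabsence] ==
                    PSEUDOABSENCE_DENSITY))
  # presence-based cap: 10% of 40 presences = 4 < 50
  pa2 <- add_pseudoabsences(obs, hauls, seed = 1, of_presences = TRUE)
  expect_equal(sum(pa2$pseudoabsence), 4)
})

test_that("no pseudoabsences where the species was observed", {
  s <- tiny_sim()
  pa <- s$obs[s$obs$pseudoabsence, , drop = FALSE]
  region_of <- setNames(s$hauls$region, s$hauls$haul_id)
  for (sp in unique(s$obs$species_id)) {
    seen <- unique(region_of[s$obs$haul_id[s$obs$present &
                                             s$obs$species_id == sp]])
    pa_regions <- unique(region_of[pa$haul_id[pa$species_id == sp]])
    expect_length(intersect(seen, pa_regions), 0)
  }
  # dropping pseudoabsence rows recovers the zero-expanded densities
  expect_true(all(s$obs$biomass_density[!s$obs$pseudoabsence &
                                          !s$obs$present] == 0))
  # pseudoabsences never alter the presence flag
  expect_true(all(!s$obs$present[s$obs$pseudoabsence]))
})

test_that("pseudoabsence sampling is deterministic under seed", {
  hauls <- rbind(make_hauls(100, region = "r1"),
                 make_hauls(100, region = "r2", id_prefix = "g"))
  catch <- data.frame(haul_id = "h001", species_id = "sp",
                      biomass_density = 1)
  obs <- expand_zeros(catch, hauls)
  a <- add_pseudoabsences(obs, hauls, seed = 42)
  b <- add_pseudoabsences(obs, hauls, seed = 42)
  expect_identical(a, b)
})

test_that("chronological split takes the first 80% per region", {
  hauls <- make_hauls(10, years = 2000:2009)
  out <- split_train_test(hauls)
  expect_equal(sort(out$year[out$train]), 2000:2007)
  expect_equal(sort(out$year[!out$train]), 2008:2009)
  # fraction 1 -> empty test set
  all_train <- split_train_test(hauls, fraction = 1)
  expect_true(all(all_train$train))
})

test_that("split is computed independently per region and is stable", {
  hauls <- rbind(make_hauls(10, region = "r1", years = 2000:2009),
                 make_hauls(20, region = "r2", years = 1995:2014,
                            id_prefix = "g"))
  out <- split_train_test(hauls)
  expect_equal(sum(out$train[out$region == "r1"]), 8)
  expect_equal(sum(out$train[out$region == "r2"]), 16)
  # permuting input rows does not change each haul's assignment
  perm <- sample(nrow(hauls))
  out2 <- split_train_test(hauls[perm, ])
  expect_equal(out2$train[match(out$haul_id, out2$haul_id)], out$train)
})

test_that("regions with fewer than five hauls go to training with warning", {
  hauls <- make_hauls(3)
  expect_warning(out <- split_train_test(hauls), "fewer than 5")
  expect_true(all(out$train))
})

test_that("species gate enforces occurrence count and training coverage", {
  n <- 600
  hauls <- split_train_test(make_hauls(n, years = 2000:2009))
  mk_obs <- function(sp, present_ids) {
    data.frame(species_id = sp, haul_id = hauls$haul_id,
               present = hauls$haul_id %in% present_ids,
               biomass_density = as.numeric(hauls$haul_id %in% present_ids),
               pseudoabsence = FALSE)
  }
  train_ids <- hauls$haul_id[hauls$train]
  test_ids <- hauls$haul_id[!hauls$train]
  obs <- rbind(mk_obs("rich", hauls$haul_id[1:250]),
               mk_obs("rare", hauls$haul_id[1:249]),
               mk_obs("late", test_ids[1:100]))
  expect_identical(gate_species(obs, hauls, min_occurrences = 250), "rich")
  # 'late' passes a lowered occurrence bar but has no training presences
  expect_false("late" %in% gate_species(obs, hauls, min_occurrences = 100))
  expect_true("rare" %in% gate_species(obs, hauls, min_occurrences = 100))
})
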