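# Harmonization of multi-survey catch data into per-species modelling
# tables: density standardization, zero expansion, near-zero
# pseudoabsence augmentation, chronological train/test splitting, and the
# minimum-occurrence gate.

#' Near-zero biomass density assigned to pseudoabsence records
#' @export
PSEUDOABSENCE_DENSITY <- 1e-10

#' Standardize raw catches to one density per haul and species
#'
#' Sums biomass over duplicate (haul, species) rows -- as arise when a
#' species is recorded separately by sex or maturity stage -- and converts
#' the summed weight to biomass density per unit area swept.
#'
#' @param catch data frame with `haul_id`, `species_id`, `weight`
#' @param hauls haul table with `haul_id`, `swept_area`
#' @return data frame with `haul_id`, `species_id`, `biomass_density`
#' @export
standardize_catches <- function(catch, hauls) {
  if (nrow(catch) == 0)
    return(data.frame(haul_id = character(), species_id = character(),
                      biomass_density = numeric()))
  unknown <- setdiff(catch$haul_id, hauls$haul_id)
  if (length(unknown))
    stop("standardize_catches: unknown haul_id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  agg <- stats::aggregate(weight ~ haul_id + species_id, data = catch,
                          FUN = sum)
  swept <- hauls$swept_area[match(agg$haul_id, hauls$haul_id)]
  if (any(swept <= 0)) stop("standardize_catches: swept_area must be > 0")
  data.frame(haul_id = agg$haul_id, species_id = agg$species_id,
             biomass_density = agg$weight / swept)
}

#' Expand catches to include observed absences
#'
#' For each species and each haul on the coast(s) where the species was
#' recorded, emits exactly one observation record: a presence with its
#' biomass density, or a zero (observed absence).  Coasts are handled
#' separately, mirroring the separate modelling of Atlantic and Pacific
#' distributions.
#'
#' @param catch standardized catch table ([standardize_catches()])
#' @param hauls haul table with `haul_id`, `coast`
#' @param species_coasts optional data frame `species_id`, `coast`
#'   assigning species to coasts; defaults to every coast where the
#'   species has at least one catch
#' @return observation table: `species_id`, `haul_id`, `present`,
#'   `biomass_density`, `pseudoabsence` (all `FALSE` here)
#' @export
expand_zeros <- function(catch, hauls, species_coasts = NULL) {
  if (is.null(species_coasts)) {
    hc <- hauls$coast[match(catch$haul_id, hauls$haul_id)]
    species_coasts <- unique(data.frame(species_id = catch$species_id,
                                        coast = hc))
  }
  out <- lapply(seq_len(nrow(species_coasts)), function(i) {
    sp <- species_coasts$species_id[i]
    co <- species_coasts$coast[i]
    h <- hauls[hauls$coast == co, , drop = FALSE]
    dens <- numeric(nrow(h))
    rows <- catch$species_id == sp & catch$haul_id %in% h$haul_id
    idx <- match(catch$haul_id[rows], h$haul_id)
    dens[idx] <- catch$biomass_density[rows]
    data.frame(species_id = sp, haul_id = h$haul_id,
               present = dens > 0, biomass_density = dens,
               pseudoabsence = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Add near-zero pseudoabsences in never-observed regions
#'
#' For each species and each region in which it was never observed, a
#' random sample of hauls receives the near-zero biomass density 1e-10
#' and a pseudoabsence flag.  The sample size is the smaller of 10% of
#' the hauls in that region and 10% of the species' total observation
#' records (both floored).  Pseudoabsence rows anchor the biomass model's
#' thermal envelope outside the observed range; they are excluded from
#' presence-absence modelling.
#'
#' @param obs observation table from [expand_zeros()]
#' @param hauls haul table with `haul_id`, `region`
#' @param seed integer seed for the haul sampling
#' @param fraction the sampling fraction (default 0.10)
#' @param of_presences if `TRUE`, cap by 10% of the species' presences
#'   instead of 10% of its total observation records
#' @return observation table with pseudoabsence rows flagged
#' @export
add_pseudoabsences <- function(obs, hauls, seed = 1L, fraction = 0.10,
                               of_presences = FALSE) {
  set.seed(seed)
  region_of <- setNames(hauls$region, hauls$haul_id)
  obs$.region <- region_of[obs$haul_id]
  for (sp in unique(obs$species_id)) {
    rows_sp <- which(obs$species_id == sp)
    seen <- unique(obs$.region[rows_sp][obs$present[rows_sp]])
    total <- if (of_presences) sum(obs$present[rows_sp]) else length(rows_sp)
    cap <- floor(fraction * total)
    for (rg in setdiff(unique(hauls$region), seen)) {
      rows_rg <- rows_sp[obs$.region[rows_sp] == rg]
      if (length(rows_rg) == 0) next    # region not in this species' table
      n_pa <- min(floor(fraction * length(rows_rg)), cap)
      if (n_pa < 1) next
      pick <- sample(rows_rg, n_pa)
      obs$biomass_density[pick] <- PSEUDOABSENCE_DENSITY
      obs$pseudoabsence[pick] <- TRUE
    }
  }
  obs$.region <- NULL
  obs
}

#' Chronological train/test split within regions
#'
#' Orders the hauls of each region by date (ties broken by haul id) and
#' assigns the first `fraction` to the training set and the remainder to
#' the testing set.  Regions with fewer than five hauls go entirely to
#' training, with a warning.
#'
#' @param hauls haul table with `haul_id`, `region`, `year`, `month` and
#'   optionally `day`
#' @param fraction training fraction (default 0.80)
#' @return `hauls` with a logical `train` column added
#' @export
split_train_test <- function(hauls, fraction = 0.80) {
  stopifnot(fraction > 0, fraction <= 1)
  day <- if ("day" %in% names(hauls)) hauls$day else 1L
  datekey <- hauls$year * 10000 + hauls$month * 100 + day
  train <- logical(nrow(hauls))
  for (rg in unique(hauls$region)) {
    idx <- which(hauls$region == rg)
    if (length(idx) < 5) {
      warning("split_train_test: region '", rg,
              "' has fewer than 5 hauls; all assigned to training")
      train[idx] <- TRUE
      next
    }
    ord <- idx[order(datekey[idx], hauls$haul_id[idx])]
    n_train <- floor(fraction * length(ord))
    train[ord[seq_len(n_train)]] <- TRUE
  }
  hauls$train <- train
  hauls
}

#' Gate species on occurrence count and training coverage
#'
#' Retains species with at least `min_occurrences` presences in the
#' observation table, dropping any whose presences fall entirely in the
#' testing split (such species cannot be fitted).
#'
#' @param obs observation table (zero-expanded)
#' @param hauls haul table carrying the `train` flag from
#'   [split_train_test()]
#' @param min_occurrences occurrence threshold (default 250)
#' @return character vector of retained species ids
#' @export
gate_species <- function(obs, hauls, min_occurrences = 250) {
  train_of <- setNames(hauls$train, hauls$haul_id)
  keep <- character()
  for (sp in unique(obs$species_id)) {
    pres <- obs$present & obs$species_id == sp
    if (sum(pres) < min_occurrences) next
    if (!any(train_of[obs$haul_id[pres]])) next
    keep <- c(keep, sp)
  }
  keep
}
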