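Package: thermshift
Title: Two-Stage Thermal Niche Models and Century-Scale Habitat Shift
    Projections for Shelf Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for projecting shifts in the thermal habitat of
    continental-shelf species over the 21st century.  Harmonizes
    multi-survey bottom-trawl catch data (zero expansion, near-zero
    pseudoabsences, chronological train/test splits), builds seven
    environmental predictors (seasonal surface/bottom temperature means,
    annual extremes, seafloor rugosity, sediment grain size in Phi units
    with inverse-distance-weighted interpolation), fits two-stage
    (hurdle-type) generalized additive niche models with a survey fixed
    effect, downscales climate-model temperature projections by the delta
    method onto an observed climatology and a fine depth-masked projection
    grid, drives the fitted models over a general-circulation-model
    ensemble to annual summer biomass fields in twenty-year bins, and
    summarizes ensemble agreement with biomass-weighted centroid shifts,
    circular directional-agreement statistics, and quantile-regression
    based uncertainty classifications.  A self-contained synthetic-world
    generator (shelf grid, temperature climatology, warming ensemble,
    multi-survey trawl sampling of species with known Gaussian thermal
    niches) supports testing and simulation studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
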