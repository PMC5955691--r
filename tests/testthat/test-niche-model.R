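test_that("gamma penalty is ln(n)/2", {
  expect_equal(gamma_penalty(exp(2)), 1)
  expect_equal(gamma_penalty(100), log(100) / 2)
  expect_equal(gamma_penalty(200) - gamma_penalty(100), log(2) / 2)
  expect_error(gamma_penalty(1), ">= 2")
})

test_that("rank AUC handles separation, ties, and brute force", {
  expect_equal(rank_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(rank_auc(c(0.9, 0.1, 0.5), c(1, 0, 0)), 1)
  # one concordant pair and one tied pair -> (1 + 0.5) / 2
  expect_equal(rank_auc(c(0.9, 0.5, 0.5), c(1, 1, 0)), 0.75)
  expect_true(is.na(rank_auc(c(0.2, 0.3), c(1, 1))))
  # brute-force pair counting oracle on random data with ties
  set.seed(12)
  scores <- sample(seq(0, 1, 0.1), 40, replace = TRUE)
  labels <- rbinom(40, 1, 0.4) == 1
  pos <- scores[labels]; neg <- scores[!labels]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(rank_auc(scores, labels), mean(pairs))
})

test_that("rank AUC is invariant under strictly increasing transforms", {
  set.seed(4)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5) == 1
  a <- rank_auc(scores, labels)
  expect_equal(rank_auc(qlogis(scores), labels), a)
  expect_equal(rank_auc(scores^3 + 2 * scores, labels), a)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(rank_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("prediction is the product of the stage components", {
  m <- tiny_model()
  s <- tiny_sim()
  nd <- s$predictors[1:50, -1]
  comp <- predict_biomass(m, nd, components = TRUE)
  expect_equal(comp$biomass, comp$p_occ * exp(comp$log_biomass))
  expect_true(all(comp$biomass >= 0))
  expect_true(all(comp$p_occ >= 0 & comp$p_occ <= 1))
  # forced arithmetic of the combination rule
  expect_equal(0.5 * exp(0), 0.5)
  expect_equal(1 * exp(log(10)), 10)
})

test_that("interpolated prediction matches exact evaluation", {
  m <- tiny_model()
  s <- tiny_sim()
  nd <- s$predictors[1:400, -1]
  nd$survey_id <- "svyA"
  exact <- predict_biomass(m, nd)
  fast <- predict_biomass(m, nd, interpolate = TRUE)
  expect_equal(fast, exact, tolerance = 1e-4)
})

test_that("unseen survey levels fall back to the reference with warning", {
  m <- tiny_model()
  s <- tiny_sim()
  nd <- s$predictors[1:5, -1]
  nd$survey_id <- "not_a_survey"
  expect_warning(p1 <- predict_biomass(m, nd), "unseen survey")
  nd$survey_id <- m$reference_survey
  expect_equal(predict_biomass(m, nd), p1)
})

test_that("fitting recovers the generating thermal optimum", {
  m <- tiny_model()
  expect_lt(abs(thermal_optimum(m) - 16), 1)
})

test_that("stage-2 survey contrast recovers the catchability ratio", {
  s <- tiny_sim()
  m <- tiny_model()
  # svyA has catchability 1, svyB 2; contrast is relative to reference
  eff <- survey_effect(m, stage = 2)
  expect_equal(nrow(eff), 1)
  truth <- if (m$reference_survey == "svyA") log(2) else -log(2)
  expect_lt(abs(eff$estimate - truth), 1.96 * eff$se + 0.1)
})

test_that("null data yields near-zero explained deviance", {
  set.seed(15)
  n <- 1500
  hauls_id <- sprintf("h%04d", 1:n)
  obs <- data.frame(species_id = "null", haul_id = hauls_id,
                    present = rbinom(n, 1, 0.4) == 1,
                    biomass_density = rlnorm(n), pseudoabsence = FALSE)
  obs$biomass_density[!obs$present] <- 0
  pred <- data.frame(haul_id = hauls_id,
                     sst_seasonal = rnorm(n, 20, 3),
                     sbt_seasonal = rnorm(n, 15, 3),
                     sbt_min = rnorm(n, 10, 2), sbt_max = rnorm(n, 20, 2),
                     sst_max = rnorm(n, 24, 2),
                     rugosity = abs(rnorm(n, 5, 2)),
                     grain_phi = runif(n, -2, 7),
                     survey_id = sample(c("a", "b"), n, TRUE))
  m <- fit_two_stage(obs, pred)
  expect_lt(m$deviance_explained[["stage1"]], 0.05)
})

test_that("refitting with permuted rows yields identical predictions", {
  s <- tiny_sim()
  o <- s$obs[s$obs$species_id == "warmfish", , drop = FALSE]
  train <- s$hauls$haul_id[s$hauls$train]
  o <- o[o$haul_id %in% train, , drop = FALSE]
  set.seed(2)
  m1 <- fit_two_stage(o, s$predictors)
  m2 <- fit_two_stage(o[sample(nrow(o)), , drop = FALSE], s$predictors)
  nd <- s$predictors[1:100, -1]
  expect_equal(predict_biomass(m1, nd), predict_biomass(m2, nd),
               tolerance = 1e-8)
})

test_that("stage 2 refuses to fit with too few positive catches", {
  s <- tiny_sim()
  o <- s$obs[s$obs$species_id == "coolfish", , drop = FALSE]
  few <- rbind(o[o$present, ][1:5, ], o[!o$present, ][1:200, ])
  expect_error(fit_two_stage(few, s$predictors), "positive catches")
})

test_that("pseudoabsence rows are excluded from the occurrence stage", {
  s <- tiny_sim()
  o <- s$obs[s$obs$species_id == "coolfish", , drop = FALSE]
  train <- s$hauls$haul_id[s$hauls$train]
  o <- o[o$haul_id %in% train, , drop = FALSE]
  m <- tiny_model()
  expect_equal(m$n[["stage1"]], sum(!o$pseudoabsence))
  expect_equal(m$n[["stage2"]], sum(o$present | o$pseudoabsence))
})

test_that("AUC evaluation flags undiscriminating and single-class cases", {
  m <- tiny_model()
  s <- tiny_sim()
  test_ids <- s$hauls$haul_id[!s$hauls$train]
  o <- s$obs[s$obs$species_id == "coolfish" &
               s$obs$haul_id %in% test_ids, , drop = FALSE]
  val <- evaluate_auc(m, o, s$predictors)
  expect_gt(val$auc, 0.75)
  expect_false(val$dropped)
  # single-class test set
  o1 <- o[o$present, , drop = FALSE]
  val1 <- evaluate_auc(m, o1, s$predictors)
  expect_true(val1$dropped)
  expect_match(val1$reason, "single-class")
})
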