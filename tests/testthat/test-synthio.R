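test_that("configuration validation names the offending field", {
  expect_error(simulationConfig(nSamples = 0), "nSamples")
  expect_error(simulationConfig(signalCorrelation = 1.2),
               "signalCorrelation")
  expect_error(simulationConfig(nGenes = 10, nSignalGenes = 11),
               "nSignalGenes")
  expect_error(simulationConfig(subtypeProportions = c(BL1 = 0.5,
                                                       IM = 0.4)),
               "subtypeProportions")
  expect_error(simulationConfig(caseNoncaseRatio = 0), "caseNoncaseRatio")
})

test_that("expression generation is deterministic and embeds the latent", {
  cfg <- simulationConfig(nSamples = 500, nGenes = 400, nSignalGenes = 8,
                          signalCorrelation = 0.99, seed = 42)
  a <- generateExpressionWithLatent(cfg)
  b <- generateExpressionWithLatent(cfg)
  expect_identical(exprValues(a$expression), exprValues(b$expression))
  expect_identical(a$latent, b$latent)

  # at target r = 0.99 and n = 500, every signal gene correlates strongly
  lg <- exprValues(logNormalize(a$expression))
  rSig <- apply(lg[a$signalGenes, , drop = FALSE], 1, cor, y = a$latent)
  expect_true(all(abs(rSig) > 0.9))

  # latent is z-scaled
  expect_equal(mean(a$latent), 0, tolerance = 1e-12)
  expect_equal(sd(a$latent), 1, tolerance = 1e-12)
})

test_that("without signal genes no gene tracks the latent", {
  cfg <- simulationConfig(nSamples = 400, nGenes = 400, nSignalGenes = 0,
                          signalCorrelation = 0.5, seed = 7)
  a <- generateExpressionWithLatent(cfg)
  expect_length(a$signalGenes, 0)
  lg <- exprValues(logNormalize(a$expression))
  rAll <- abs(apply(lg, 1, cor, y = a$latent))
  # null max |r| over 400 genes at n = 400: far below any signal level
  expect_lt(max(rAll), 0.25)
})

test_that("clinical cohort honors censoring target and hazard effects", {
  sim <- simulateClinicalOnly(3, n = 4000, censoringRate = 0.6)
  expect_equal(1 - mean(sim$clinical$dfs_event), 0.6, tolerance = 0.05)
  expect_true(all(sim$clinical$dfs_time > 0))

  # zero censoring: every DFS event observed
  sim0 <- simulateClinicalOnly(3, n = 200, censoringRate = 0)
  expect_true(all(sim0$clinical$dfs_event == 1L))

  # unknown covariate term rejected by name
  bad <- simulateClinicalOnly(3, n = 50)
  expect_error(generateClinicalCohort(
    simulationConfig(nSamples = 50, logHrEffects = c(bogus = 1), seed = 1),
    bad$latent[1:50], bad$subtypes[1:50]), "bogus")

  # a binary log-2 hazard effect is recovered by Cox at large n
  simHr <- simulateClinicalOnly(11, n = 2000,
                                effects = c(treatment = log(2)),
                                censoringRate = 0)
  cl <- simHr$clinical
  fit <- weightedCoxFit(cl$dfs_time, cl$dfs_event,
                        data.frame(cm = as.numeric(cl$treatment == "CM")))
  expect_equal(unname(exp(fit$coef["cm"])), 2, tolerance = 0.15)
})

test_that("endpoint events are nested within DFS", {
  sim <- simulateClinicalOnly(5, n = 800, censoringRate = 0.5)
  cl <- sim$clinical
  expect_true(all(cl$bcfi_event <= cl$dfs_event))
  expect_true(all(cl$os_event <= cl$dfs_event))
  expect_true(all(cl$drfi_event <= cl$dfs_event))
  expect_true(sum(cl$bcfi_event) > 0)
})

test_that("case-cohort sampling includes all cases at the target ratio", {
  sim <- simulateClinicalOnly(13, n = 800, censoringRate = 0.85)
  cc <- caseCohortSample(sim$clinical, ratio = 3, seed = 2)
  expect_true(all(cc$included[cc$case]))
  expect_true(all(cc$sampling_fraction[cc$case] == 1))
  nCase <- sum(cc$case)
  nNonInc <- sum(cc$included & !cc$case)
  # granularity: each stratum rounds (and floors at one sample)
  strata <- attr(cc, "strata")
  expect_lte(abs(nNonInc - 3 * nCase), nrow(strata))
  # recorded fraction equals the empirical inclusion proportion exactly
  for (s in unique(cc$stratum_id[!cc$case])) {
    mem <- cc[cc$stratum_id == s, ]
    expect_equal(unique(mem$sampling_fraction),
                 sum(mem$included) / nrow(mem))
  }
})

test_that("case-cohort sampling saturates and records small fractions", {
  # ratio exceeding available non-cases: everyone in, fractions 1
  co <- manualCohort(nCase = 30, nNonCase = 10)
  cc <- caseCohortSample(co, ratio = 3, seed = 1)
  expect_true(all(cc$included))
  expect_true(all(cc$sampling_fraction == 1))

  # single stratum, 20 non-cases, 5 sampled -> fraction 0.25, weight 4
  co2 <- manualCohort(nCase = 1, nNonCase = 20)
  cc2 <- caseCohortSample(co2, ratio = 5, seed = 1)
  expect_equal(sum(cc2$included & !cc2$case), 5)
  expect_equal(unique(cc2$sampling_fraction[!cc2$case]), 0.25)
  expect_error(caseCohortSample(co2, ratio = 0), "ratio")
})

test_that("marker set generation is deterministic, disjoint and guarded", {
  cfg <- simulationConfig(nGenes = 2000, markersPerSubtype = 20, seed = 9)
  gs1 <- generateSubtypeGeneSets(cfg)
  gs2 <- generateSubtypeGeneSets(cfg)
  expect_identical(subtypeSets(gs1), subtypeSets(gs2))
  all6 <- unlist(subtypeSets(gs1), use.names = FALSE)
  expect_length(all6, 6 * 40)
  expect_false(anyDuplicated(all6) > 0)
  # marker genes never collide with signal genes (head vs tail layout)
  ex <- generateExpressionWithLatent(cfg, gs1)
  expect_length(intersect(ex$signalGenes, all6), 0)
  expect_error(generateSubtypeGeneSets(
    simulationConfig(nGenes = 100, nSignalGenes = 0,
                     markersPerSubtype = 20, seed = 1)),
    "insufficient genes")
})
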