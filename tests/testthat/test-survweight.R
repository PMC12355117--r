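test_that("Horvitz-Thompson weights invert the stratum sampling fractions", {
  co <- manualCohort(nCase = 1, nNonCase = 20)
  cc <- caseCohortSample(co, ratio = 5, seed = 1)  # 5 of 20 sampled
  w <- computeHTWeights(cc)
  expect_equal(unname(w[cc$sample_id[cc$case]]), 1)
  expect_equal(unname(w[setdiff(names(w), cc$sample_id[cc$case])]),
               rep(4, 5))
  expect_length(w, 6)                 # excluded samples absent

  ccAll <- caseCohortSample(manualCohort(10, 5), ratio = 3, seed = 1)
  expect_true(all(computeHTWeights(ccAll) == 1))

  ccBad <- cc
  ccBad$sampling_fraction[2] <- 0
  ccBad$included[2] <- TRUE
  expect_error(computeHTWeights(ccBad), "\\(0, 1\\]")
})

test_that("weighted KM reproduces the hand-computed product-limit curve", {
  km <- weightedKM(c(1, 2, 3), c(1, 1, 0))[["all"]]
  expect_equal(kmEstimateAt(km, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(kmEstimateAt(km, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(kmEstimateAt(km, 3), 1 / 3, tolerance = 1e-12)
  expect_equal(kmEstimateAt(km, 0), 1)
  expect_equal(kmEstimateAt(km, 1.5), 2 / 3)   # step function
  expect_equal(kmEstimateAt(km, 2.5), 1 / 3)
  expect_warning(kmEstimateAt(km, 10), "beyond last")

  expect_warning(kmF <- weightedKM(c(1, 2), c(0, 0))[["all"]],
                 "no events")
  expect_true(all(kmF$surv == 1))
  expect_error(weightedKM(c(0, 1), c(1, 1)), "positive")
})

test_that("a weight of two equals duplicating the subject", {
  set.seed(44)
  tm <- round(rexp(40), 3) + 0.01
  ev <- rbinom(40, 1, 0.7)
  w <- rep(1, 40); w[7] <- 2
  dupT <- c(tm, tm[7]); dupE <- c(ev, ev[7])
  kmW <- weightedKM(tm, ev, w)[["all"]]
  kmD <- weightedKM(dupT, dupE)[["all"]]
  expect_equal(kmW$surv, kmD$surv, tolerance = 1e-12)
  expect_equal(kmW$atRisk, kmD$atRisk, tolerance = 1e-12)
})

test_that("weighted Cox with unit weights matches the reference fit", {
  set.seed(50)
  n <- 150
  x <- rnorm(n); z <- rbinom(n, 1, 0.5)
  tm <- rexp(n, 0.1 * exp(0.5 * x)); ev <- rbinom(n, 1, 0.8)
  wf <- weightedCoxFit(tm, ev, data.frame(x = x, z = z))
  ref <- survival::coxph(survival::Surv(tm, ev) ~ x + z, ties = "breslow")
  expect_equal(unname(wf$coef), unname(coef(ref)), tolerance = 1e-8)
  expect_true(all(wf$ciLower < wf$hr & wf$hr < wf$ciUpper))
})

test_that("integer weights equal row duplication under Breslow ties", {
  set.seed(51)
  n <- 80
  x <- rnorm(n)
  tm <- rexp(n, exp(0.3 * x)); ev <- rbinom(n, 1, 0.75)
  w <- sample(1:3, n, replace = TRUE)
  idx <- rep(seq_len(n), w)
  wf <- weightedCoxFit(tm, ev, data.frame(x = x), weights = w)
  df <- weightedCoxFit(tm[idx], ev[idx], data.frame(x = x[idx]))
  expect_equal(wf$coef, df$coef, tolerance = 1e-8)
})

test_that("preconditions and non-convergence are explicit errors", {
  tm <- rexp(20) + 0.01; ev <- rep(1L, 20)
  expect_error(weightedCoxFit(tm, ev, data.frame(k = rep(1, 20))),
               "constant covariate")
  expect_error(weightedCoxFit(tm, c(rep(0L, 19), 1L),
                              data.frame(a = rnorm(20), b = rnorm(20))),
               "too few events")
  # perfectly separating covariate: monotone likelihood
  tmS <- sort(rexp(30)) + 0.01
  expect_error(suppressWarnings(
    weightedCoxFit(tmS, rep(1L, 30), data.frame(x = -seq_len(30)))),
    "did not converge")
})

test_that("null-covariate Wald p values are uniform", {
  set.seed(53)
  ps <- replicate(120, {
    n <- 100
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7); x <- rnorm(n)
    suppressWarnings(
      weightedCoxFit(tm, ev, data.frame(x = x))$waldP[["x"]])
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("interaction HR satisfies its algebraic identity and recovers truth", {
  set.seed(60)
  n <- 4000
  x <- rbinom(n, 1, 0.5); m <- rbinom(n, 1, 0.5)
  # HR for x is 2.0 when m = 0 and 0.5 when m = 1 -> hrInter = 0.25
  lp <- log(2) * x + log(0.25) * x * m
  tm <- rexp(n, 0.05 * exp(lp))
  wf <- weightedCoxFit(tm, rep(1L, n), data.frame(x = x, m = m),
                       interactions = "x:m")
  ir <- interactionHRTest(wf, "x", "m")
  expect_equal(ir$hrInter, ir$hrStratum1 / ir$hrStratum0,
               tolerance = 1e-10)
  expect_equal(ir$hrInter, unname(exp(wf$coef["x:m"])), tolerance = 1e-12)
  expect_equal(ir$hrInter, 0.25, tolerance = 0.2)
  expect_lt(ir$waldP, 0.001)

  wf0 <- weightedCoxFit(tm, rep(1L, n), data.frame(x = x, m = m))
  expect_error(interactionHRTest(wf0, "x", "m"), "product term")
})

test_that("BH adjustment matches hand and brute-force step-up results", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bhAdjust(p), bhBruteForce(p), tolerance = 1e-12)
  }
})

test_that("LR p for the feature of interest comes from nested fits", {
  set.seed(62)
  n <- 300
  x <- rnorm(n); z <- rnorm(n)
  tm <- rexp(n, 0.1 * exp(0.8 * x)); ev <- rep(1L, n)
  wf <- weightedCoxFit(tm, ev, data.frame(x = x, z = z),
                       featureOfInterest = "x")
  expect_lt(wf$lrP, 1e-6)
  expect_equal(wf$lrDf, 1)
  wfNull <- weightedCoxFit(tm, ev, data.frame(z = z),
                           featureOfInterest = "z")
  expect_gt(wfNull$lrP, 0.01)
})
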