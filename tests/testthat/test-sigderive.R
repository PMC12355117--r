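test_that("train/test split has the configured sizes and is reproducible", {
  ids <- sprintf("p%03d", 1:141)
  sp <- splitTrainTest(ids, 95 / 141, seed = 8)
  expect_length(sp$train, 95)
  expect_length(sp$test, 46)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitTrainTest(ids, 95 / 141, seed = 8))

  sp2 <- splitTrainTest(sprintf("p%02d", 1:10), 0.5, seed = 1)
  expect_length(sp2$train, 5)
  expect_error(splitTrainTest(ids[1:3], 0.5, 1), "4 samples")
  expect_error(splitTrainTest(ids, 0.999, 1), "degenerate")
})

test_that("stability filter selects perfectly correlated genes and drops flat ones", {
  y <- setNames(c(1, 2, 3, 4), sprintf("s%02d", 1:4))
  m <- toyExpression(rbind(c(1, 2, 3, 4),      # identical to response
                           c(7, 7, 7, 7)),     # flat: r treated as 0
                     units = "log_normalized")
  cfg <- derivationConfig(nIterations = 1, subsampleFraction = 0.99,
                          seed = 3)
  out <- stabilityCorrelationFilter(m, y, cfg)
  expect_identical(out$candidates, "g01")
  expect_equal(unname(out$frequency), c(1, 0))
})

test_that("independent noise genes are selected far below the frequency cutoff", {
  set.seed(15)
  n <- 150
  m <- toyExpression(matrix(rnorm(30 * n), 30, n),
                     units = "log_normalized",
                     samples = sprintf("s%03d", 1:n))
  y <- setNames(rnorm(n), sampleIds(m))
  cfg <- derivationConfig(nIterations = 200, seed = 5)
  out <- stabilityCorrelationFilter(m, y, cfg)
  expect_length(out$candidates, 0)
  # selection frequencies stay well below the 75% candidate cutoff
  expect_true(all(out$frequency < 0.75))
  expect_lt(mean(out$frequency), 0.1)
})

test_that("raising the correlation threshold never enlarges the candidate set", {
  cfgSim <- simulationConfig(nSamples = 80, nGenes = 300,
                             nSignalGenes = 10, signalCorrelation = 0.4,
                             seed = 19)
  ex <- generateExpressionWithLatent(cfgSim)
  lg <- logNormalize(ex$expression)
  loose <- stabilityCorrelationFilter(lg, ex$latent,
    derivationConfig(nIterations = 150, rThreshold = 0.2, seed = 2))
  tight <- stabilityCorrelationFilter(lg, ex$latent,
    derivationConfig(nIterations = 150, rThreshold = 0.3, seed = 2))
  expect_true(all(tight$candidates %in% loose$candidates))
  expect_true(all(tight$frequency <= loose$frequency))
})

test_that("a lone candidate equal to the response gets coefficient ~1 at tiny penalty", {
  x <- seq(1, 20)
  z <- as.numeric(scale(x))
  m <- toyExpression(matrix(x, 1, 20), units = "log_normalized",
                     samples = sprintf("s%02d", 1:20))
  y <- setNames(z, sampleIds(m))
  sig <- fitPenalizedSignature(m, y,
    derivationConfig(lambdaGrid = c(1e-4, 1e-5), seed = 1))
  expect_identical(geneIds(sig), "g01")
  expect_equal(unname(sigCoefficients(sig)), 1, tolerance = 1e-3)
})

test_that("an extreme penalty yields an explicit empty-signature error", {
  set.seed(6)
  m <- toyExpression(matrix(rnorm(100), 5, 20), units = "log_normalized",
                     samples = sprintf("s%02d", 1:20))
  y <- setNames(rnorm(20), sampleIds(m))
  expect_error(fitPenalizedSignature(m, y,
    derivationConfig(lambdaGrid = c(1e3, 2e3), seed = 1)),
    "empty signature")
})

test_that("duplicated candidates share the coefficient of a single gene", {
  set.seed(31)
  n <- 60
  g <- rnorm(n)
  y <- setNames(as.numeric(scale(g + rnorm(n, sd = 0.2))),
                sprintf("s%02d", 1:n))
  single <- toyExpression(matrix(g, 1, n), units = "log_normalized",
                          samples = names(y))
  dup <- toyExpression(rbind(g, g), units = "log_normalized",
                       samples = names(y))
  cfg <- derivationConfig(lambdaGrid = c(0.01, 0.0100001), seed = 2)
  b1 <- sum(sigCoefficients(fitPenalizedSignature(single, y, cfg)))
  b2 <- sum(sigCoefficients(fitPenalizedSignature(dup, y, cfg)))
  expect_equal(b2, b1, tolerance = 0.02)
})

test_that("validation enforces train/test disjointness and flags degenerate n", {
  sig <- GeneSignature("g01", 1,
                       meta = list(center = c(g01 = 0), scale = c(g01 = 1),
                                   trainIds = c("s01", "s02")))
  m <- toyExpression(matrix(c(1, 2, 3), 1, 3), units = "log_normalized",
                     samples = c("s01", "s03", "s04"))
  y <- setNames(c(1, 2, 3), sampleIds(m))
  expect_error(validateSignature(sig, m, y), "overlap")

  m2 <- toyExpression(matrix(c(1, 2, 3), 1, 3), units = "log_normalized",
                      samples = c("s03", "s04", "s05"))
  y2 <- setNames(exprValues(m2)[1, ], sampleIds(m2))
  val <- validateSignature(sig, m2, y2)
  expect_equal(val$r, 1, tolerance = 1e-12)

  m3 <- toyExpression(matrix(c(1, 2), 1, 2), units = "log_normalized",
                      samples = c("s03", "s04"))
  y3 <- setNames(c(5, 9), sampleIds(m3))
  expect_warning(validateSignature(sig, m3, y3), "degenerate")
})

test_that("end-to-end derivation recovers signal genes and validates held-out", {
  cfgSim <- simulationConfig(nSamples = 120, nGenes = 800,
                             nSignalGenes = 15, signalCorrelation = 0.5,
                             seed = 23)
  ex <- generateExpressionWithLatent(cfgSim)
  lg <- logNormalize(ex$expression)
  sig <- deriveSignature(lg, ex$latent,
                         derivationConfig(nIterations = 300, seed = 23))
  cand <- sig@meta$candidates
  expect_gte(mean(ex$signalGenes %in% cand), 0.7)
  expect_gte(sig@meta$validation_r, 0.6)
  expect_length(intersect(sig@meta$trainIds, sig@meta$testIds), 0)
  # identical configuration reproduces the identical signature
  sig2 <- deriveSignature(lg, ex$latent,
                          derivationConfig(nIterations = 300, seed = 23))
  expect_identical(sigCoefficients(sig), sigCoefficients(sig2))
})

test_that("the selected gene set is stable across CV fold seeds", {
  cfgSim <- simulationConfig(nSamples = 120, nGenes = 600,
                             nSignalGenes = 15, signalCorrelation = 0.5,
                             seed = 29)
  ex <- generateExpressionWithLatent(cfgSim)
  lg <- logNormalize(ex$expression)
  filt <- stabilityCorrelationFilter(lg, ex$latent,
    derivationConfig(nIterations = 300, seed = 29))
  cexpr <- phosphoSig:::exprSubset(lg, genes = filt$candidates)
  sets <- lapply(1:3, function(s)
    geneIds(fitPenalizedSignature(cexpr, ex$latent,
                                  derivationConfig(seed = s))))
  jac <- combn(3, 2, function(ij)
    length(intersect(sets[[ij[1]]], sets[[ij[2]]])) /
      length(union(sets[[ij[1]]], sets[[ij[2]]])))
  expect_gte(min(jac), 0.8)
})
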