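# shared fixtures, all generated in code

toyExpression <- function(values, units = "raw_counts",
                          genes = sprintf("g%02d", seq_len(nrow(values))),
                          samples = sprintf("s%02d",
                                            seq_len(ncol(values)))) {
  ExpressionMatrix(matrix(values, nrow = length(genes),
                          dimnames = list(genes, samples)), units)
}

# clinical cohort without the expression stage (latent and subtypes drawn
# directly), for survival-focused tests
simulateClinicalOnly <- function(seed, n = 600, effects = numeric(0),
                                 censoringRate = 0.8, ...) {
  cfg <- simulationConfig(nSamples = n, logHrEffects = effects,
                          censoringRate = censoringRate, seed = seed, ...)
  set.seed(seed + 500000L)
  lat <- setNames(rnorm(n), sprintf("s%04d", seq_len(n)))
  sub <- setNames(sample(names(cfg$subtypeProportions), n, TRUE,
                         cfg$subtypeProportions), names(lat))
  list(cfg = cfg, latent = lat, subtypes = sub,
       clinical = generateClinicalCohort(cfg, lat, sub))
}

# hand-rolled clinical table with full control over cases and strata
manualCohort <- function(nCase, nNonCase, size = "T1", nodal = "N0",
                         age = "60+", trt = "CM") {
  n <- nCase + nNonCase
  structure(data.frame(
    sample_id = sprintf("m%03d", seq_len(n)),
    dfs_time = rep(10, n), dfs_event = rep(c(1L, 0L), c(nCase, nNonCase)),
    bcfi_time = rep(10, n),
    bcfi_event = rep(c(1L, 0L), c(nCase, nNonCase)),
    os_time = rep(10, n), os_event = 0L,
    drfi_time = rep(10, n), drfi_event = 0L,
    tumor_size_category = size, nodal_category = nodal,
    age_category = age, treatment = trt,
    tils_percent = 20, true_subtype = "BL1", true_pjnk = 0,
    stringsAsFactors = FALSE),
    class = c("ClinicalCohort", "data.frame"))
}

# independent brute-force BH step-up oracle
bhBruteForce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
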