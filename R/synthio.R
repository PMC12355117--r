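## Synthetic cohort generation: expression with a latent phospho level,
## subtype centroid structure, clinical endpoints under proportional
## hazards, and stratified case-cohort sampling.

#' Simulation configuration
#'
#' Collects and validates every parameter of the synthetic cohort
#' generator. The defaults describe the reference simulation used
#' throughout the package's tests: a cohort with five true molecular
#' subtypes, a latent phospho-protein level to which a known subset of
#' genes is correlated, and proportional-hazards survival with optional
#' subtype/pJNK/treatment effects.
#'
#' @param nSamples number of samples.
#' @param nGenes number of genes.
#' @param nSignalGenes number of genes correlated with the latent phospho
#'   level (may be 0 for null simulations).
#' @param signalCorrelation target Pearson correlation, in (0,1), between
#'   each signal gene's log-scale expression and the latent level.
#' @param subtypeProportions named probabilities over the simulated true
#'   subtypes; must sum to 1. Defaults cover BL1/IM/M/LAR/MSL (no true BL2
#'   samples; BL2 marker sets are still generated so the six-way classifier
#'   and its reassignment rule are exercised).
#' @param centroidShift log2-scale mean shift applied to a subtype's
#'   positive (+) and negative (-) marker genes in samples of that subtype.
#' @param baselineHazard baseline event hazard per month (> 0).
#' @param logHrEffects named numeric vector of log hazard ratios. Allowed
#'   term names: `"pjnk"`, `"treatment"`, `"subtype<NAME>"` (e.g.
#'   `"subtypeIM"`), and interactions of two such atoms joined by `":"`
#'   (e.g. `"pjnk:treatment"`, `"subtypeIM:pjnk"`).
#' @param censoringRate target fraction of censored observations in
#'   \[0, 1); censoring is administrative (uniform accrual over
#'   `(0, tau)` with `tau` solved to hit the target rate in expectation).
#' @param caseNoncaseRatio target non-cases per case in the case-cohort
#'   sample (the reference design uses 3).
#' @param seed integer seed; all generator randomness flows from it.
#' @param markersPerSubtype positive and negative marker genes allocated
#'   per subtype by [generateSubtypeGeneSets()].
#' @param bioSd biological log2-scale standard deviation per gene; 0 gives
#'   noiseless centroid samples.
#' @param poissonNoise if `TRUE`, counts are Poisson draws around the
#'   log-normal mean; if `FALSE`, counts are the rounded means.
#' @param bcfiFraction,osFraction,drfiFraction probability that a primary
#'   (DFS) event also counts as a BCFI / OS / DRFI event; the remaining
#'   endpoints are censored at the DFS time, preserving endpoint nesting.
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(nSamples = 60, nGenes = 300, seed = 7)
#' @export
simulationConfig <- function(nSamples = 600L, nGenes = 2000L,
                             nSignalGenes = 25L, signalCorrelation = 0.5,
                             subtypeProportions = c(BL1 = 0.25, IM = 0.25,
                                                    M = 0.25, LAR = 0.15,
                                                    MSL = 0.10),
                             centroidShift = 1, baselineHazard = 0.02,
                             logHrEffects = numeric(0),
                             censoringRate = 0.8, caseNoncaseRatio = 3,
                             seed = 1L, markersPerSubtype = 20L,
                             bioSd = 1, poissonNoise = TRUE,
                             bcfiFraction = 0.85, osFraction = 0.6,
                             drfiFraction = 0.7) {
  bad <- function(field, why)
    stop(sprintf("invalid SimulationConfig field '%s': %s", field, why),
         call. = FALSE)
  if (!is.numeric(nSamples) || nSamples < 1) bad("nSamples", "must be >= 1")
  if (!is.numeric(nGenes) || nGenes < 1) bad("nGenes", "must be >= 1")
  if (!is.numeric(nSignalGenes) || nSignalGenes < 0)
    bad("nSignalGenes", "must be >= 0")
  if (nSignalGenes > nGenes)
    bad("nSignalGenes", "must not exceed nGenes")
  if (!is.numeric(signalCorrelation) || signalCorrelation <= 0 ||
      signalCorrelation >= 1)
    bad("signalCorrelation", "must lie in (0, 1)")
  if (is.null(names(subtypeProportions)) ||
      !all(names(subtypeProportions) %in% SUBTYPE_NAMES))
    bad("subtypeProportions", sprintf("names must be among %s",
                                      paste(SUBTYPE_NAMES, collapse = ", ")))
  if (abs(sum(subtypeProportions) - 1) > 1e-12)
    bad("subtypeProportions", "must sum to 1")
  if (any(subtypeProportions < 0)) bad("subtypeProportions", "negative entry")
  if (!is.numeric(centroidShift) || centroidShift < 0)
    bad("centroidShift", "must be >= 0")
  if (!is.numeric(baselineHazard) || baselineHazard <= 0)
    bad("baselineHazard", "must be > 0")
  if (length(logHrEffects) && is.null(names(logHrEffects)))
    bad("logHrEffects", "must be a named numeric vector")
  if (!is.numeric(censoringRate) || censoringRate < 0 || censoringRate >= 1)
    bad("censoringRate", "must lie in [0, 1)")
  if (!is.numeric(caseNoncaseRatio) || caseNoncaseRatio <= 0)
    bad("caseNoncaseRatio", "must be > 0")
  if (!is.numeric(seed) || abs(seed) >= 2^31)
    bad("seed", "must be a 32-bit integer")
  if (!is.numeric(markersPerSubtype) || markersPerSubtype < 1)
    bad("markersPerSubtype", "must be >= 1")
  if (!is.numeric(bioSd) || bioSd < 0) bad("bioSd", "must be >= 0")
  for (f in c("bcfiFraction", "osFraction", "drfiFraction")) {
    v <- get(f)
    if (!is.numeric(v) || v <= 0 || v > 1) bad(f, "must lie in (0, 1]")
  }
  structure(list(
    nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
    nSignalGenes = as.integer(nSignalGenes),
    signalCorrelation = signalCorrelation,
    subtypeProportions = subtypeProportions,
    centroidShift = centroidShift, baselineHazard = baselineHazard,
    logHrEffects = logHrEffects, censoringRate = censoringRate,
    caseNoncaseRatio = caseNoncaseRatio, seed = as.integer(seed),
    markersPerSubtype = as.integer(markersPerSubtype), bioSd = bioSd,
    poissonNoise = isTRUE(poissonNoise), bcfiFraction = bcfiFraction,
    osFraction = osFraction, drfiFraction = drfiFraction),
    class = "SimulationConfig")
}

## derive a deterministic substream seed without 32-bit overflow
subSeed <- function(seed, offset)
  as.integer((as.numeric(seed) + offset) %% 2147483647)

simGeneIds <- function(n) sprintf("g%04d", seq_len(n))
simSampleIds <- function(n) sprintf("s%04d", seq_len(n))

#' Generate synthetic marker gene sets for the six TNBC subtypes
#'
#' Allocates disjoint positive/negative marker sets for BL1, BL2, IM, M,
#' LAR and MSL from the tail of the gene-id vector (signal genes occupy the
#' head, so marker and signal genes never overlap). The allocation is a
#' deterministic function of the configuration, so identical configurations
#' yield identical sets.
#'
#' @param config a [simulationConfig()].
#' @param geneIds gene identifier vector (defaults to the generator's own
#'   ids).
#' @return A [SubtypeGeneSets-class] with `markersPerSubtype` positive and
#'   negative genes per subtype.
#' @export
generateSubtypeGeneSets <- function(config,
                                    geneIds = simGeneIds(config$nGenes)) {
  k <- config$markersPerSubtype
  need <- config$nSignalGenes + 2L * k * length(SUBTYPE_NAMES)
  if (length(geneIds) < need)
    stop(sprintf("insufficient genes: need %d for %d signal + 6x%d marker pairs, have %d",
                 need, config$nSignalGenes, k, length(geneIds)),
         call. = FALSE)
  pool <- rev(geneIds)  # tail of the gene universe
  sets <- list()
  off <- 0L
  for (s in SUBTYPE_NAMES) {
    up <- pool[off + seq_len(k)]
    dn <- pool[off + k + seq_len(k)]
    off <- off + 2L * k
    sets[[s]] <- list(up = up, dn = dn)
  }
  SubtypeGeneSets(sets)
}

#' Generate a count matrix carrying a latent phospho level and centroid
#' structure
#'
#' Expression is simulated on the log2 scale as gene baseline + biological
#' noise; each signal gene shares a latent standard-normal phospho level
#' with mixing weight `signalCorrelation` (so its log-scale correlation
#' with the latent approaches that target), and each subtype's marker
#' genes are shifted by `centroidShift` (up-markers +, down-markers -) in
#' samples of that subtype. Counts are Poisson draws around the
#' exponentiated log means (or the rounded means when `poissonNoise =
#' FALSE`). Identical configurations yield bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @param geneSets optional [SubtypeGeneSets-class] whose marker genes
#'   receive centroid shifts; omit for a cohort without subtype structure.
#' @return A list with components `expression` (an
#'   [ExpressionMatrix-class], raw counts), `latent` (named numeric,
#'   z-scaled latent phospho level per sample), `signalGenes` (character),
#'   and `subtypeLabels` (named character, the true subtype per sample).
#' @export
generateExpressionWithLatent <- function(config, geneSets = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$nSamples; p <- config$nGenes
  gids <- simGeneIds(p); sids <- simSampleIds(n)

  props <- config$subtypeProportions
  subtype <- sample(names(props), n, replace = TRUE, prob = props)
  names(subtype) <- sids

  latentRaw <- rnorm(n)
  latent <- if (n > 1 && sd(latentRaw) > 0)
    as.numeric(scale(latentRaw)) else latentRaw
  names(latent) <- sids

  signalGenes <- if (config$nSignalGenes > 0)
    gids[seq_len(config$nSignalGenes)] else character(0)

  mu <- runif(p, 4, 10)
  if (length(signalGenes)) mu[seq_along(signalGenes)] <- runif(
    length(signalGenes), 6, 10)

  eps <- matrix(rnorm(p * n), p, n, dimnames = list(gids, sids))
  logx <- mu + config$bioSd * eps
  if (length(signalGenes)) {
    rho <- config$signalCorrelation
    i <- seq_along(signalGenes)
    logx[i, ] <- mu[i] + config$bioSd *
      (rho * matrix(latent, length(i), n, byrow = TRUE) +
       sqrt(1 - rho^2) * eps[i, , drop = FALSE])
  }
  if (!is.null(geneSets)) {
    sets <- subtypeSets(geneSets)
    for (s in names(sets)) {
      idx <- which(subtype == s)
      if (!length(idx)) next
      up <- intersect(sets[[s]]$up, gids)
      dn <- intersect(sets[[s]]$dn, gids)
      logx[up, idx] <- logx[up, idx] + config$centroidShift
      logx[dn, idx] <- logx[dn, idx] - config$centroidShift
    }
  }
  lam <- 2^logx
  counts <- if (config$poissonNoise)
    matrix(rpois(p * n, lam), p, n, dimnames = dimnames(logx))
  else round(lam)
  list(expression = ExpressionMatrix(counts, "raw_counts"),
       latent = latent, signalGenes = signalGenes,
       subtypeLabels = subtype)
}

## resolve one linear-predictor atom to a numeric column
lpAtom <- function(atom, data) {
  if (atom == "pjnk") return(data$pjnk)
  if (atom == "treatment") return(as.numeric(data$treatment == "CM"))
  if (startsWith(atom, "subtype")) {
    s <- sub("^subtype", "", atom)
    if (s %in% SUBTYPE_NAMES)
      return(as.numeric(data$subtype == s))
  }
  stop(sprintf("unknown covariate term in logHrEffects: '%s'", atom),
       call. = FALSE)
}

buildLinearPredictor <- function(effects, data) {
  lp <- numeric(nrow(data))
  for (term in names(effects)) {
    atoms <- strsplit(term, ":", fixed = TRUE)[[1]]
    col <- Reduce(`*`, lapply(atoms, lpAtom, data = data))
    lp <- lp + effects[[term]] * col
  }
  lp
}

## expected event probability under exponential event times with
## per-sample rate lambda and administrative censoring U(0, tau)
expectedEventFraction <- function(lt, rate) {
  x <- rate * exp(lt)
  mean(1 - (1 - exp(-x)) / x)
}

#' Generate a synthetic clinical cohort under proportional hazards
#'
#' Event times for the primary endpoint (DFS) are exponential with hazard
#' `baselineHazard * exp(lp)`, where the linear predictor is assembled
#' from `config$logHrEffects` over the latent phospho level, treatment
#' arm, true subtype indicators and their products. Censoring is
#' administrative: censoring times are uniform on `(0, tau)` with `tau`
#' solved so the expected censored fraction equals
#' `config$censoringRate`. BCFI events are a thinned subset of DFS events
#' (cases for the case-cohort design are BCFI events); OS and DRFI are
#' further thinned, preserving the nesting of the four endpoints.
#' Stratification factors (tumor size T1/T2/T3, nodal N0/N1-3/N4plus, age
#' in four bins, treatment CM/no-CM) and TIL percentages (higher in IM
#' tumors) are drawn independently of survival unless named in
#' `logHrEffects`.
#'
#' @param config a [simulationConfig()].
#' @param latent named numeric latent phospho vector (z-scaled), as from
#'   [generateExpressionWithLatent()].
#' @param subtypes named character vector of true subtype labels, aligned
#'   with `latent`.
#' @return A `data.frame` of class `ClinicalCohort` with sample ids, the
#'   four endpoints (`*_time` in months, `*_event` 0/1), stratification
#'   factors, treatment, `tils` percent, and the synthetic truth columns
#'   `true_subtype` and `true_pjnk`.
#' @export
generateClinicalCohort <- function(config, latent, subtypes) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (length(latent) != length(subtypes))
    stop("latent and subtypes lengths differ", call. = FALSE)
  n <- length(latent)
  sids <- if (!is.null(names(latent))) names(latent) else simSampleIds(n)
  set.seed(subSeed(config$seed, 7919))  # distinct substream from expression

  treatment <- sample(c("CM", "no-CM"), n, replace = TRUE)
  tumorSize <- sample(c("T1", "T2", "T3"), n, replace = TRUE,
                      prob = c(0.5, 0.4, 0.1))
  nodal <- sample(c("N0", "N1-3", "N4plus"), n, replace = TRUE,
                  prob = c(0.6, 0.3, 0.1))
  age <- sample(c("<40", "40-<50", "50-<60", "60+"), n, replace = TRUE,
                prob = c(0.15, 0.3, 0.3, 0.25))
  tils <- ifelse(subtypes == "IM",
                 100 * rbeta(n, 5, 3), 100 * rbeta(n, 2, 6))

  covars <- data.frame(pjnk = as.numeric(latent), treatment = treatment,
                       subtype = as.character(subtypes))
  lp <- buildLinearPredictor(config$logHrEffects, covars)
  rate <- config$baselineHazard * exp(lp)
  eventTime <- rexp(n, rate)

  if (config$censoringRate <= 0) {
    dfsTime <- eventTime; dfsEvent <- rep(1L, n)
  } else {
    target <- 1 - config$censoringRate
    f <- function(logTau) expectedEventFraction(logTau, rate) - target
    logTau <- uniroot(f, lower = log(1e-6 / config$baselineHazard),
                      upper = log(1e6 / config$baselineHazard),
                      extendInt = "upX", tol = 1e-10)$root
    cens <- runif(n, 0, exp(logTau))
    dfsEvent <- as.integer(eventTime <= cens)
    dfsTime <- pmin(eventTime, cens)
  }
  thin <- function(frac) as.integer(dfsEvent == 1L & runif(n) <= frac)
  bcfiEvent <- thin(config$bcfiFraction)
  osEvent   <- thin(config$osFraction)
  drfiEvent <- thin(config$drfiFraction)

  structure(data.frame(
    sample_id = sids,
    dfs_time = dfsTime, dfs_event = dfsEvent,
    bcfi_time = dfsTime, bcfi_event = bcfiEvent,
    os_time = dfsTime, os_event = osEvent,
    drfi_time = dfsTime, drfi_event = drfiEvent,
    tumor_size_category = tumorSize, nodal_category = nodal,
    age_category = age, treatment = treatment,
    tils_percent = tils,
    true_subtype = as.character(subtypes), true_pjnk = as.numeric(latent),
    stringsAsFactors = FALSE, row.names = NULL),
    class = c("ClinicalCohort", "data.frame"))
}

#' Stratified case-cohort sampling
#'
#' All cases (BCFI events) are included. Non-cases are sampled without
#' replacement within strata formed by the full cross of the four
#' stratification factors (tumor size, nodal status, age bin, treatment),
#' at a common target fraction chosen so the overall non-case:case ratio
#' approximates `ratio`; every non-empty stratum contributes at least one
#' sampled non-case so each unit keeps a positive inclusion probability.
#' Per-stratum realized sampling fractions are recorded (these, inverted,
#' are the Horvitz-Thompson weights).
#'
#' @param cohort a `ClinicalCohort` (needs `bcfi_event` and the four
#'   stratification factor columns).
#' @param ratio target non-cases per case (> 0).
#' @param seed integer seed for the non-case draws.
#' @return A `data.frame` of class `CaseCohortSample` with columns
#'   `sample_id`, `case`, `stratum_id`, `included`, `sampling_fraction`,
#'   plus a per-stratum summary in `attr(, "strata")` (strata with no
#'   non-cases are recorded with fraction 1 and `flagged = TRUE`).
#' @export
caseCohortSample <- function(cohort, ratio = 3, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0) stop("ratio must be > 0",
                                             call. = FALSE)
  case <- cohort$bcfi_event == 1L
  if (!any(case)) stop("cohort contains no cases (BCFI events)",
                       call. = FALSE)
  factorKey <- paste(cohort$tumor_size_category, cohort$nodal_category,
                     cohort$age_category, cohort$treatment, sep = "|")
  stratum <- paste0(factorKey, "|", ifelse(case, "case", "noncase"))

  included <- case          # every case is in
  fraction <- rep(1, nrow(cohort))

  nCases <- sum(case)
  idxNon <- which(!case)
  nNon <- length(idxNon)
  strataRows <- list()
  if (nNon > 0) {
    f <- min(1, ratio * nCases / nNon)
    set.seed(seed)
    for (s in unique(stratum[idxNon])) {
      members <- idxNon[stratum[idxNon] == s]
      ns <- min(length(members), max(1L, round(f * length(members))))
      take <- if (ns == length(members)) members
              else sample(members, ns)
      included[take] <- TRUE
      fraction[members] <- ns / length(members)
      strataRows[[s]] <- data.frame(stratum_id = s,
                                    n_total = length(members),
                                    n_included = ns,
                                    sampling_fraction = ns / length(members),
                                    flagged = FALSE)
    }
  }
  for (s in unique(stratum[case])) {
    strataRows[[s]] <- data.frame(stratum_id = s, n_total = sum(stratum == s),
                                  n_included = sum(stratum == s),
                                  sampling_fraction = 1, flagged = FALSE)
    # flag case strata whose factor cell has no non-cases at all
    cell <- sub("\\|case$", "|noncase", s)
    if (!cell %in% stratum)
      strataRows[[s]]$flagged <- TRUE
  }
  out <- structure(data.frame(sample_id = cohort$sample_id, case = case,
                              stratum_id = stratum, included = included,
                              sampling_fraction = fraction,
                              stringsAsFactors = FALSE, row.names = NULL),
                   class = c("CaseCohortSample", "data.frame"))
  attr(out, "strata") <- do.call(rbind, unname(strataRows))
  out
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper chaining [generateSubtypeGeneSets()],
#' [generateExpressionWithLatent()], [generateClinicalCohort()] and
#' [caseCohortSample()] under one configuration.
#'
#' @param config a [simulationConfig()].
#' @return A list with `geneSets`, `expression`, `latent`, `signalGenes`,
#'   `subtypeLabels`, `clinical` and `caseCohort`.
#' @export
simulateCohort <- function(config) {
  geneSets <- generateSubtypeGeneSets(config)
  ex <- generateExpressionWithLatent(config, geneSets)
  clinical <- generateClinicalCohort(config, ex$latent, ex$subtypeLabels)
  cc <- caseCohortSample(clinical, ratio = config$caseNoncaseRatio,
                         seed = subSeed(config$seed, 104729))
  c(list(geneSets = geneSets), ex,
    list(clinical = clinical, caseCohort = cc))
}
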