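## End-to-end orchestration: simulate -> preprocess -> derive -> score ->
## classify -> weighted survival -> report.

#' Pipeline configuration
#'
#' @param simulation a [simulationConfig()] for simulate mode, or `NULL`
#'   to read inputs from the paths below.
#' @param derivation a [derivationConfig()].
#' @param expressionPath,clinicalPath,geneSetsPath input paths (required
#'   when `simulation` is `NULL`): expression TSV, clinical CSV, GMT.
#' @param signaturePath optional pre-derived signature TSV (used in
#'   non-simulate mode when the clinical table carries no phospho
#'   response to derive against).
#' @param outdir output directory for report artifacts, or `NULL` to
#'   skip writing.
#' @param tilThreshold TILs percentage above which (strictly) a tumor
#'   counts as TIL-high; in (0, 100).
#' @param immuneRule how immune-related tumors are defined: by IM
#'   subtype call, by TILs above the threshold, or by either (default).
#' @param endpoints endpoints to analyse (subset of dfs, bcfi, os, drfi).
#' @param readThreshold minimum mapped reads per sample.
#' @param prevalenceFraction minimum fraction of samples in which a gene
#'   must be expressed.
#' @param seed master seed for every stage.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           derivation = derivationConfig(),
                           expressionPath = NULL, clinicalPath = NULL,
                           geneSetsPath = NULL, signaturePath = NULL,
                           outdir = NULL,
                           tilThreshold = 30,
                           immuneRule = c("either", "IM_subtype",
                                          "TILs_gt_threshold"),
                           endpoints = "dfs",
                           readThreshold = 200000,
                           prevalenceFraction = 0.7, seed = 1L) {
  immuneRule <- match.arg(immuneRule)
  if (tilThreshold <= 0 || tilThreshold >= 100)
    stop("tilThreshold must lie in (0, 100)", call. = FALSE)
  if (!all(endpoints %in% c("dfs", "bcfi", "os", "drfi")))
    stop("endpoints must be among dfs, bcfi, os, drfi", call. = FALSE)
  if (is.null(simulation)) {
    for (p in c(expressionPath, clinicalPath, geneSetsPath))
      if (is.null(p) || !file.exists(p))
        stop("non-simulate mode requires existing expression, clinical ",
             "and gene-set paths; missing: ", p, call. = FALSE)
  }
  structure(list(simulation = simulation, derivation = derivation,
                 expressionPath = expressionPath,
                 clinicalPath = clinicalPath, geneSetsPath = geneSetsPath,
                 signaturePath = signaturePath,
                 outdir = outdir, tilThreshold = tilThreshold,
                 immuneRule = immuneRule, endpoints = endpoints,
                 readThreshold = readThreshold,
                 prevalenceFraction = prevalenceFraction,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Flag immune-related tumors
#'
#' A tumor is immune-related when its subtype call is IM, when its TILs
#' percentage strictly exceeds the threshold (a tumor at exactly the
#' threshold is not immune-related), or either, per the configured rule.
#'
#' @param calls subtype calls: the data frame from [assignSubtype()] or a
#'   character vector of calls.
#' @param tilsPercent numeric TILs percentages aligned with `calls`
#'   (may be omitted when `rule = "IM_subtype"`).
#' @param rule `"either"`, `"IM_subtype"` or `"TILs_gt_threshold"`.
#' @param threshold TILs cutoff (default 30).
#' @return A logical vector.
#' @export
defineImmuneRelated <- function(calls, tilsPercent = NULL,
                                rule = c("either", "IM_subtype",
                                         "TILs_gt_threshold"),
                                threshold = 30) {
  rule <- match.arg(rule)
  if (is.data.frame(calls)) calls <- calls$call
  isIM <- calls == "IM"
  if (rule == "IM_subtype") return(isIM)
  if (is.null(tilsPercent) || anyNA(tilsPercent))
    stop("rule '", rule, "' needs complete TILs percentages",
         call. = FALSE)
  if (length(tilsPercent) != length(calls))
    stop("calls and tilsPercent lengths differ", call. = FALSE)
  tilHigh <- tilsPercent > threshold
  if (rule == "TILs_gt_threshold") tilHigh else (isIM | tilHigh)
}

## polynomial rolling hash over a character scalar, for config provenance
configHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

pipelineCovariates <- function(clin) {
  data.frame(
    sizeGt2cm = as.numeric(clin$tumor_size_category != "T1"),
    nodalPos = as.numeric(clin$nodal_category != "N0"),
    treatmentCM = as.numeric(clin$treatment == "CM"))
}

#' Run the full analysis pipeline
#'
#' In simulate mode (the default configuration) the stages are: cohort
#' simulation; sample and gene filtering; log-normalization; signature
#' derivation against the latent phospho level with held-out validation;
#' cohort scoring and median dichotomization; six-way centroid subtyping
#' with BL2 reassignment; TIME classification; immune-related flagging;
#' and, per endpoint, Horvitz-Thompson-weighted Kaplan-Meier curves by
#' pJNK group plus weighted Cox models with subtype x pJNK interaction
#' tests (BH-adjusted across the five subtypes) and a treatment x pJNK
#' interaction within immune-related tumors. Every random draw flows
#' from the configured seeds, so identical configurations give
#' byte-identical serialized reports.
#'
#' @param cfg a [pipelineConfig()].
#' @return An `AnalysisReport` list; also written as JSON/TSV under
#'   `cfg$outdir` when set.
#' @export
runFullPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  stage <- "input"
  res <- tryCatch({
    if (!is.null(cfg$simulation)) {
      sim <- simulateCohort(cfg$simulation)
      expr <- sim$expression; clinical <- sim$clinical
      geneSets <- sim$geneSets; ccs <- sim$caseCohort
      response <- setNames(clinical$true_pjnk, clinical$sample_id)
    } else {
      expr <- readExpression(cfg$expressionPath)
      clinical <- readClinical(cfg$clinicalPath)
      geneSets <- gmtToSubtypeGeneSets(readGMT(cfg$geneSetsPath))
      ccs <- caseCohortSample(clinical, seed = cfg$seed)
      response <- if ("true_pjnk" %in% names(clinical))
        setNames(clinical$true_pjnk, clinical$sample_id) else NULL
    }

    stage <- "preprocess"
    fs <- filterSamplesByMappedReads(expr, cfg$readThreshold)
    fg <- filterGenesByPrevalence(fs$expression, cfg$prevalenceFraction)
    logExpr <- logNormalize(fg$expression)
    keep <- sampleIds(logExpr)
    clinical <- clinical[match(keep, clinical$sample_id), , drop = FALSE]

    stage <- "derive"
    signature <- NULL
    if (!is.null(response)) {
      dcfg <- cfg$derivation
      dcfg$seed <- subSeed(cfg$seed, dcfg$seed)
      signature <- deriveSignature(logExpr, response[keep], dcfg)
    } else if (!is.null(cfg$signaturePath)) {
      signature <- readSignature(cfg$signaturePath)
    } else {
      stop("no phospho response to derive against and no signaturePath ",
           "supplied", call. = FALSE)
    }

    stage <- "score"
    scores <- scoreSamples(signature, logExpr)
    groups <- dichotomizeByMedian(scores)
    pjnkLow <- setNames(as.numeric(groups$label == "low"),
                        groups$sampleIds)

    stage <- "classify"
    subtypeScores <- computeSubtypeScores(logExpr, geneSets)
    calls <- assignSubtype(subtypeScores)
    tcfg <- timeConfig(immuneSet = subtypeSets(geneSets)$IM$up,
                       stromalSet = subtypeSets(geneSets)$M$up)
    timeCalls <- classifyTime(logExpr, tcfg)
    immuneRelated <- defineImmuneRelated(calls, clinical$tils_percent,
                                         cfg$immuneRule,
                                         cfg$tilThreshold)

    stage <- "survival"
    weights <- computeHTWeights(ccs)
    weights <- weights[names(weights) %in% keep]
    inc <- match(names(weights), clinical$sample_id)
    clinInc <- clinical[inc, , drop = FALSE]
    covars <- pipelineCovariates(clinInc)
    lowInc <- pjnkLow[names(weights)]
    callsInc <- calls$call[match(names(weights), calls$sample_id)]
    immInc <- immuneRelated[match(names(weights), clinical$sample_id)]

    endpointResults <- list()
    for (ep in cfg$endpoints) {
      tm <- clinInc[[paste0(ep, "_time")]]
      ev <- clinInc[[paste0(ep, "_event")]]
      km <- weightedKM(tm, ev, weights,
                       group = ifelse(lowInc == 1, "low", "high"))
      km60 <- vapply(km, kmEstimateAt, numeric(1), horizon = 60)

      overall <- tryCatch(
        weightedCoxFit(tm, ev, cbind(pjnkLow = lowInc, covars), weights,
                       featureOfInterest = "pjnkLow"),
        error = function(e) e$message)

      subtypeRows <- list()
      for (s in c("BL", "IM", "M", "LAR", "MSL")) {
        row <- tryCatch({
          feat <- as.numeric(callsInc == s)
          wfit <- weightedCoxFit(
            tm, ev, cbind(inSubtype = feat, pjnkLow = lowInc, covars),
            weights, interactions = "inSubtype:pjnkLow")
          ir <- interactionHRTest(wfit, "inSubtype", "pjnkLow")
          data.frame(subtype = s, hr_low = ir$hrStratum1,
                     hr_high = ir$hrStratum0, hr_inter = ir$hrInter,
                     ci_lower = ir$ciLower, ci_upper = ir$ciUpper,
                     p_inter = ir$waldP)
        }, error = function(e)
          data.frame(subtype = s, hr_low = NA, hr_high = NA,
                     hr_inter = NA, ci_lower = NA, ci_upper = NA,
                     p_inter = NA))
        subtypeRows[[s]] <- row
      }
      subtypeTab <- do.call(rbind, subtypeRows)
      ok <- !is.na(subtypeTab$p_inter)
      subtypeTab$q_inter <- NA_real_
      if (any(ok)) subtypeTab$q_inter[ok] <- bhAdjust(subtypeTab$p_inter[ok])

      cmInter <- tryCatch({
        sel <- which(immInc)
        wfit <- weightedCoxFit(
          tm[sel], ev[sel],
          data.frame(treatmentCM = covars$treatmentCM[sel],
                     pjnkLow = lowInc[sel]),
          weights[sel], interactions = "treatmentCM:pjnkLow")
        ir <- interactionHRTest(wfit, "treatmentCM", "pjnkLow")
        list(hr_cm_low = ir$hrStratum1, hr_cm_high = ir$hrStratum0,
             hr_inter = ir$hrInter, p_inter = ir$waldP,
             q_inter = bhAdjust(ir$waldP))
      }, error = function(e) list(error = conditionMessage(e)))

      endpointResults[[ep]] <- list(
        km_rate_60mo = as.list(km60),
        km_curves = lapply(km, function(cv)
          list(time = cv$time, surv = cv$surv)),
        overall_pjnk = if (is.character(overall)) list(error = overall)
          else list(hr = unname(overall$hr["pjnkLow"]),
                    ci_lower = unname(overall$ciLower["pjnkLow"]),
                    ci_upper = unname(overall$ciUpper["pjnkLow"]),
                    wald_p = unname(overall$waldP["pjnkLow"]),
                    lr_p = overall$lrP,
                    q = unname(bhAdjust(overall$waldP["pjnkLow"]))),
        subtype_interactions = subtypeTab,
        cm_interaction_immune_related = cmInter)
    }

    stage <- "report"
    cfgJson <- jsonlite::toJSON(cfg[setdiff(names(cfg), "outdir")],
                                auto_unbox = TRUE, digits = NA,
                                force = TRUE)
    report <- list(
      provenance = list(seed = cfg$seed, config_hash = configHash(cfgJson),
                        package_version =
                          as.character(utils::packageVersion("phosphoSig"))),
      counts = list(
        n_input = length(sampleIds(expr)),
        n_after_sample_filter = length(sampleIds(expr)) -
          length(fs$excluded),
        n_analyzed = length(keep),
        n_case_cohort = length(weights),
        genes_analyzed = length(geneIds(logExpr)),
        subtype = as.list(table(calls$call)),
        time = as.list(table(timeCalls)),
        immune_related = sum(immuneRelated),
        pjnk_low = sum(pjnkLow)),
      signature = if (is.null(signature)) NULL else list(
        n_genes = length(geneIds(signature)),
        validation_r = signature@meta$validation_r,
        validation_p = signature@meta$validation_p,
        lambda = signature@meta$lambda),
      subtype_calls = calls,
      scores = data.frame(sample_id = scores$sampleIds,
                          score = scores$scores,
                          pjnk_group = as.character(groups$label)),
      endpoints = endpointResults)
    class(report) <- "AnalysisReport"

    if (!is.null(cfg$outdir)) {
      dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(unclass(report),
                           file.path(cfg$outdir, "report.json"),
                           auto_unbox = TRUE, digits = 10, force = TRUE,
                           dataframe = "columns")
      write.csv(report$scores, file.path(cfg$outdir, "scores.csv"),
                row.names = FALSE, quote = FALSE)
      utils::write.table(calls, file.path(cfg$outdir, "subtype_calls.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      if (!is.null(signature))
        writeSignature(signature, file.path(cfg$outdir, "signature.tsv"))
    }
    report
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport\n")
  cat(sprintf("  samples analyzed: %d (case-cohort: %d)\n",
              x$counts$n_analyzed, x$counts$n_case_cohort))
  if (!is.null(x$signature))
    cat(sprintf("  signature: %d genes, held-out r = %.3f\n",
                x$signature$n_genes, x$signature$validation_r))
  cat("  subtype counts:",
      paste(sprintf("%s=%d", names(x$counts$subtype),
                    unlist(x$counts$subtype)), collapse = " "), "\n")
  cat("  endpoints analyzed:", paste(names(x$endpoints), collapse = ", "),
      "\n")
  invisible(x)
}
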