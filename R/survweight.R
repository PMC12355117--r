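## Case-cohort weighted survival analysis: Horvitz-Thompson weights,
## weighted Kaplan-Meier, weighted Cox with robust variance, subgroup
## interaction tests and Benjamini-Hochberg correction.

#' Horvitz-Thompson weights from a case-cohort sample
#'
#' Each included sample receives the inverse of its stratum's sampling
#' fraction; cases (fraction 1) therefore get weight 1. Samples not
#' included in the case-cohort sample are absent from the output.
#'
#' @param ccs a `CaseCohortSample` from [caseCohortSample()].
#' @return A named numeric vector of weights for the included samples.
#' @export
computeHTWeights <- function(ccs) {
  stopifnot(inherits(ccs, "CaseCohortSample") ||
            all(c("sample_id", "included", "sampling_fraction") %in%
                names(ccs)))
  inc <- ccs[ccs$included, , drop = FALSE]
  if (any(inc$sampling_fraction <= 0 | inc$sampling_fraction > 1))
    stop("sampling fractions must lie in (0, 1]", call. = FALSE)
  setNames(1 / inc$sampling_fraction, inc$sample_id)
}

#' Weighted Kaplan-Meier curves
#'
#' Product-limit estimator with weighted event and at-risk sums,
#' `S(t) = prod_{t_i <= t} (1 - d_i / Y_i)`; with unit weights this is the
#' classical Kaplan-Meier estimator. One curve per group level.
#'
#' @param time positive event/censoring times.
#' @param event 0/1 event indicators.
#' @param weights positive case weights (default 1).
#' @param group optional grouping vector; omitted means a single curve.
#' @return A named list of `WeightedKMCurve` objects, each with `time`,
#'   `surv`, `atRisk` (weighted), `events` (weighted), `maxTime` and
#'   `group`. A group without any event yields a flat curve with a
#'   warning.
#' @export
weightedKM <- function(time, event, weights = NULL, group = NULL) {
  n <- length(time)
  if (any(time <= 0)) stop("times must be strictly positive",
                           call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(event) != n || length(weights) != n)
    stop("time, event and weights lengths differ", call. = FALSE)
  if (is.null(group)) group <- rep("all", n)
  out <- list()
  for (g in unique(as.character(group))) {
    idx <- which(as.character(group) == g)
    if (sum(event[idx]) == 0)
      warning(sprintf("group '%s' has no events; returning flat curve", g))
    d <- data.frame(time = time[idx], event = event[idx], w = weights[idx])
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d,
                            weights = d$w, se.fit = FALSE, conf.type = "none")
    out[[g]] <- structure(list(time = sf$time, surv = sf$surv,
                               atRisk = sf$n.risk, events = sf$n.event,
                               maxTime = max(d$time), group = g),
                          class = "WeightedKMCurve")
  }
  out
}

#' @export
print.WeightedKMCurve <- function(x, ...) {
  cat(sprintf("WeightedKMCurve '%s': %d time points, final S = %.3f\n",
              x$group, length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at a horizon
#'
#' Right-continuous step-function lookup, e.g. the 5-year rate at
#' `horizon = 60` months. Beyond the last observed time the last value is
#' carried forward with a warning.
#'
#' @param curve a `WeightedKMCurve`.
#' @param horizon non-negative time (months).
#' @return The survival probability at `horizon`.
#' @export
kmEstimateAt <- function(curve, horizon) {
  stopifnot(inherits(curve, "WeightedKMCurve"), horizon >= 0)
  if (horizon > curve$maxTime)
    warning("horizon beyond last observed time; carrying last value forward")
  i <- findInterval(horizon, curve$time)
  if (i == 0) 1 else curve$surv[i]
}

#' Weighted Cox proportional hazards fit
#'
#' Maximizes the weighted partial likelihood (Breslow ties by default, so
#' integer weights are exactly equivalent to row duplication) with robust
#' sandwich standard errors; with unit weights this reproduces the
#' standard Cox model. The likelihood-ratio p value for the feature of
#' interest compares the weighted log partial likelihoods of the full
#' model and the model with the feature's terms removed (a
#' quasi-likelihood ratio under non-unit weights).
#'
#' @param time,event survival outcome (times > 0, events 0/1).
#' @param covariates `data.frame` of covariate columns (numeric or
#'   factor); no column may be constant.
#' @param weights positive weights (default 1).
#' @param featureOfInterest character vector of terms whose removal
#'   defines the nested null model for the likelihood-ratio test; terms
#'   are covariate column names or interactions written `"a:b"`.
#' @param interactions character vector of interaction terms `"a:b"` to
#'   add to the model.
#' @param ties `"breslow"` (default, required for exact duplication
#'   equivalence) or `"efron"`.
#' @return A `WeightedCoxFit` list: `terms`, `coef`, `robustSE`, `hr`,
#'   `ciLower`, `ciUpper` (95%), `waldP`, `lrP`, `lrDf`, `n`,
#'   `nWeighted`, `nEvents` and the underlying `coxph` object in `fit`.
#' @export
weightedCoxFit <- function(time, event, covariates, weights = NULL,
                           featureOfInterest = NULL,
                           interactions = character(0),
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  n <- length(time)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(event) == n, nrow(covariates) == n,
            length(weights) == n)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  const <- vapply(covariates, function(x) length(unique(x)) < 2, logical(1))
  if (any(const))
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "), call. = FALSE)
  rhs <- paste(c(names(covariates), interactions), collapse = " + ")
  mm <- model.matrix(stats::as.formula(paste("~", rhs)), data = covariates)
  nPar <- ncol(mm) - 1L
  if (sum(event) < nPar)
    stop(sprintf("too few events (%d) for %d parameters", sum(event), nPar),
         call. = FALSE)
  d <- cbind(data.frame(.time = time, .event = event, .w = weights),
             covariates)
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(form, data = d, weights = d$.w, robust = TRUE,
                         ties = ties,
                         control = survival::coxph.control(
                           eps = 1e-12, toler.chol = 1e-14,
                           iter.max = 50))
  beta <- coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    stop("weighted Cox fit did not converge (possible monotone likelihood ",
         "or separation); coefficients: ",
         paste(sprintf("%s=%.2f", names(beta), beta), collapse = ", "),
         call. = FALSE)
  rse <- setNames(sqrt(diag(fit$var)), names(beta))  # robust sandwich
  zcrit <- qnorm(0.975)
  lrP <- lrDf <- NA_real_
  if (!is.null(featureOfInterest)) {
    keep <- setdiff(c(names(covariates), interactions), featureOfInterest)
    ## interactions involving a removed main effect go with it
    keep <- keep[!vapply(strsplit(keep, ":", fixed = TRUE), function(a)
      any(a %in% featureOfInterest), logical(1))]
    ll1 <- fit$loglik[2]
    if (length(keep)) {
      form0 <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                       paste(keep, collapse = " + ")))
      fit0 <- survival::coxph(form0, data = d, weights = d$.w,
                              ties = ties)
      ll0 <- fit0$loglik[2]
      lrDf <- length(beta) - length(coef(fit0))
    } else {
      fit0 <- survival::coxph(survival::Surv(.time, .event) ~ 1, data = d,
                              weights = d$.w, ties = ties)
      ll0 <- fit0$loglik[1]
      lrDf <- length(beta)
    }
    lrP <- pchisq(2 * (ll1 - ll0), df = lrDf, lower.tail = FALSE)
  }
  structure(list(terms = names(beta), coef = beta, robustSE = rse,
                 hr = exp(beta),
                 ciLower = exp(beta - zcrit * rse),
                 ciUpper = exp(beta + zcrit * rse),
                 waldP = 2 * pnorm(-abs(beta / rse)),
                 lrP = lrP, lrDf = lrDf,
                 featureOfInterest = featureOfInterest,
                 n = n, nWeighted = sum(weights),
                 nEvents = sum(event), ties = ties, fit = fit),
            class = "WeightedCoxFit")
}

#' @export
print.WeightedCoxFit <- function(x, ...) {
  cat(sprintf("WeightedCoxFit: n = %d (weighted %.1f), events = %d\n",
              x$n, x$nWeighted, x$nEvents))
  tab <- data.frame(coef = x$coef, robustSE = x$robustSE, HR = x$hr,
                    lo95 = x$ciLower, hi95 = x$ciUpper, waldP = x$waldP)
  print(round(tab, 4))
  if (!is.na(x$lrP))
    cat(sprintf("LR p (feature: %s) = %.4g on %d df\n",
                paste(x$featureOfInterest, collapse = ", "), x$lrP, x$lrDf))
  invisible(x)
}

#' Subgroup interaction hazard-ratio test
#'
#' From a fit containing `feature`, a 0/1 `modifier` and their product
#' term, reports the feature's hazard ratio within each modifier stratum
#' and their ratio `hrInter = hr(modifier = 1) / hr(modifier = 0) =
#' exp(beta_interaction)` (the stratum coded 1 is the numerator — pass
#' e.g. the pJNK-low indicator as modifier to obtain HR_low / HR_high),
#' with a Wald p value from the robust standard error of the interaction
#' coefficient.
#'
#' @param wfit a `WeightedCoxFit` whose model includes `feature`,
#'   `modifier` and `feature:modifier`.
#' @param feature,modifier names of the two (numeric, 0/1-coded) model
#'   columns.
#' @return An `InteractionResult` list: `hrStratum1`, `hrStratum0`,
#'   `hrInter`, `ciLower`, `ciUpper`, `waldP`.
#' @export
interactionHRTest <- function(wfit, feature, modifier) {
  stopifnot(inherits(wfit, "WeightedCoxFit"))
  intName <- if (paste0(feature, ":", modifier) %in% wfit$terms)
    paste0(feature, ":", modifier)
  else if (paste0(modifier, ":", feature) %in% wfit$terms)
    paste0(modifier, ":", feature)
  else stop(sprintf("model contains no %s x %s product term", feature,
                    modifier), call. = FALSE)
  if (!feature %in% wfit$terms)
    stop(sprintf("model lacks the main effect '%s'", feature),
         call. = FALSE)
  bF <- wfit$coef[[feature]]
  bI <- wfit$coef[[intName]]
  se <- wfit$robustSE[[intName]]
  zcrit <- qnorm(0.975)
  structure(list(hrStratum1 = exp(bF + bI), hrStratum0 = exp(bF),
                 hrInter = exp(bI),
                 ciLower = exp(bI - zcrit * se),
                 ciUpper = exp(bI + zcrit * se),
                 waldP = 2 * pnorm(-abs(bI / se)),
                 feature = feature, modifier = modifier),
            class = "InteractionResult")
}

#' @export
print.InteractionResult <- function(x, ...) {
  cat(sprintf(
    "InteractionResult %s x %s: HR[1] = %.3f, HR[0] = %.3f,\n  HRinter = %.3f (95%% CI %.3f-%.3f), Wald p = %.4g\n",
    x$feature, x$modifier, x$hrStratum1, x$hrStratum0, x$hrInter,
    x$ciLower, x$ciUpper, x$waldP))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving in the input.
#'
#' @param pvals numeric p values in \[0, 1\].
#' @return Adjusted q values, same order as the input.
#' @export
bhAdjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvals, method = "BH")
}
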