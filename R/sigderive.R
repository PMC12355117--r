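## Signature derivation: stability correlation filtering over stochastic
## subsamples, then elastic-net regression with cross-validated penalty,
## validated on a held-out split.

#' Derivation configuration
#'
#' Parameters of the signature derivation procedure. The defaults are the
#' reference settings: 1000 stochastic subsamples of one third of the
#' training samples, candidate genes required to show |Pearson r| > 0.25
#' with the phospho response in at least 75% of subsamples, elastic-net
#' mixing 0.5 with 7-fold cross-validation, and a train:test split of
#' 95:46 (fraction 95/141).
#'
#' @param nIterations number of stochastic subsamples.
#' @param subsampleFraction fraction of training samples drawn (without
#'   replacement) per iteration, in (0, 1); subsample size is rounded and
#'   floored at 3.
#' @param rThreshold absolute Pearson correlation a gene must exceed
#'   (strictly) to count as selected in one draw.
#' @param frequencyThreshold fraction of draws, in (0, 1], in which a gene
#'   must be selected to become a candidate.
#' @param enetMixing elastic-net mixing parameter alpha in \[0, 1\]
#'   (1 = lasso, 0 = ridge).
#' @param cvFolds cross-validation folds for the penalty search (>= 2).
#' @param lambdaGrid `"auto"` (100 log-spaced values from the smallest
#'   all-zero penalty down to 1e-4 of it) or a numeric vector of penalties.
#' @param trainFraction fraction of samples assigned to training.
#' @param seed integer seed governing the split, the subsample draws and
#'   the CV fold assignment.
#' @return A validated list of class `DerivationConfig`.
#' @export
derivationConfig <- function(nIterations = 1000L, subsampleFraction = 1 / 3,
                             rThreshold = 0.25, frequencyThreshold = 0.75,
                             enetMixing = 0.5, cvFolds = 7L,
                             lambdaGrid = "auto", trainFraction = 95 / 141,
                             seed = 1L) {
  stopifnot(nIterations >= 1,
            subsampleFraction > 0, subsampleFraction < 1,
            rThreshold > 0,
            frequencyThreshold > 0, frequencyThreshold <= 1,
            enetMixing >= 0, enetMixing <= 1,
            cvFolds >= 2,
            trainFraction > 0, trainFraction < 1)
  if (!identical(lambdaGrid, "auto") &&
      (!is.numeric(lambdaGrid) || any(lambdaGrid <= 0)))
    stop("lambdaGrid must be \"auto\" or a vector of positive penalties",
         call. = FALSE)
  structure(list(nIterations = as.integer(nIterations),
                 subsampleFraction = subsampleFraction,
                 rThreshold = rThreshold,
                 frequencyThreshold = frequencyThreshold,
                 enetMixing = enetMixing, cvFolds = as.integer(cvFolds),
                 lambdaGrid = lambdaGrid, trainFraction = trainFraction,
                 seed = as.integer(seed)),
            class = "DerivationConfig")
}

#' Split samples into training and testing sets
#'
#' @param samples character vector of sample ids (>= 4).
#' @param trainFraction training fraction; the training set has
#'   `round(trainFraction * n)` samples, the test set the remainder.
#' @param seed integer seed; identical seeds give identical splits.
#' @return A list with `train` and `test` id vectors (disjoint,
#'   exhaustive).
#' @export
splitTrainTest <- function(samples, trainFraction = 95 / 141, seed = 1L) {
  n <- length(samples)
  if (n < 4) stop("need at least 4 samples to split", call. = FALSE)
  nTrain <- round(trainFraction * n)
  if (nTrain < 1 || nTrain >= n)
    stop(sprintf("degenerate split: %d train / %d test", nTrain, n - nTrain),
         call. = FALSE)
  set.seed(seed)
  train <- sample(samples, nTrain)
  list(train = train, test = setdiff(samples, train))
}

alignResponse <- function(expr, response) {
  if (is.null(names(response)))
    stop("response must be named by sample id", call. = FALSE)
  if (!setequal(names(response), sampleIds(expr)))
    stop("sample ids of expression and response do not match", call. = FALSE)
  response[sampleIds(expr)]
}

#' Stability correlation filter
#'
#' Repeatedly subsamples the training cohort and computes each gene's
#' Pearson correlation with the continuous response; a gene becomes a
#' candidate if its absolute correlation strictly exceeds
#' `cfg$rThreshold` in at least `cfg$frequencyThreshold` of the draws.
#' Genes with zero variance within a draw contribute a correlation of 0
#' for that draw.
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized`), training
#'   samples only.
#' @param response named numeric response (e.g. latent phospho level),
#'   sample ids matching `expr`.
#' @param cfg a [derivationConfig()].
#' @return A list: `candidates` (gene ids) and `frequency` (named numeric
#'   selection frequency for every gene, for audit).
#' @export
stabilityCorrelationFilter <- function(expr, response, cfg) {
  stopUnits(expr, "log_normalized", "stabilityCorrelationFilter")
  y <- alignResponse(expr, response)
  x <- t(exprValues(expr))              # samples x genes
  n <- nrow(x)
  m <- max(3L, round(cfg$subsampleFraction * n))
  if (m > n) stop("subsample size exceeds sample count", call. = FALSE)
  set.seed(subSeed(cfg$seed, 61))
  hits <- numeric(ncol(x))
  for (i in seq_len(cfg$nIterations)) {
    idx <- sample.int(n, m)
    r <- suppressWarnings(as.numeric(cor(x[idx, , drop = FALSE], y[idx])))
    r[!is.finite(r)] <- 0
    hits <- hits + (abs(r) > cfg$rThreshold)
  }
  freq <- setNames(hits / cfg$nIterations, colnames(x))
  list(candidates = names(freq)[freq >= cfg$frequencyThreshold],
       frequency = freq)
}

## z-score a genes x samples matrix with supplied (training) statistics
zApply <- function(v, center, scale) (v - center) / scale

#' Fit the penalized signature on candidate genes
#'
#' Elastic-net regression of the response on z-scored candidate-gene
#' expression. The penalty is chosen by minimum mean cross-validated
#' error over the grid; genes with zero coefficient at the selected
#' penalty are dropped.
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized`) restricted
#'   to candidate genes, training samples only.
#' @param response named numeric response aligned to `expr`.
#' @param cfg a [derivationConfig()].
#' @return A [GeneSignature-class]; `meta` carries the selected lambda,
#'   the candidate list, and the training z-statistics (`center`,
#'   `scale`) used to transform new data.
#' @export
fitPenalizedSignature <- function(expr, response, cfg) {
  stopUnits(expr, "log_normalized", "fitPenalizedSignature")
  y <- alignResponse(expr, response)
  v <- exprValues(expr)
  if (nrow(v) < 1) stop("no candidate genes to fit", call. = FALSE)
  center <- rowMeans(v)
  scl <- apply(v, 1, sd)
  if (any(scl == 0))
    stop("zero-variance candidate gene(s): ",
         paste(rownames(v)[scl == 0], collapse = ", "), call. = FALSE)
  x <- t(zApply(v, center, scl))        # samples x genes, z-scored
  ## glmnet needs >= 2 columns; pad single-candidate fits with a null
  ## column that can never enter the model
  pad <- ncol(x) == 1L
  if (pad) x <- cbind(x, ".pad" = 0)
  set.seed(subSeed(cfg$seed, 271))
  foldid <- sample(rep(seq_len(cfg$cvFolds), length.out = nrow(x)))
  args <- list(x = x, y = as.numeric(y), family = "gaussian",
               alpha = cfg$enetMixing, standardize = FALSE,
               foldid = foldid)
  if (identical(cfg$lambdaGrid, "auto")) {
    args$nlambda <- 100L
    args$lambda.min.ratio <- 1e-4
  } else args$lambda <- sort(cfg$lambdaGrid, decreasing = TRUE)
  cvfit <- do.call(glmnet::cv.glmnet, args)
  beta <- coef(cvfit, s = "lambda.min")[, 1]
  beta <- beta[setdiff(names(beta), c("(Intercept)", ".pad"))]
  keep <- beta != 0
  if (!any(keep))
    stop("empty signature: all coefficients zero at the selected penalty",
         call. = FALSE)
  GeneSignature(names(beta)[keep], beta[keep],
                meta = list(config = cfg,
                            candidates = rownames(v),
                            lambda = cvfit$lambda.min,
                            center = center[names(beta)[keep]],
                            scale = scl[names(beta)[keep]]))
}

#' Validate a signature on held-out samples
#'
#' Scores the test samples with [scoreSamples()] using the signature's
#' frozen training z-statistics and reports the Pearson correlation with
#' the held-out response.
#'
#' @param sig a [GeneSignature-class] (its `meta$trainIds`, when present,
#'   must not overlap the test samples).
#' @param testExpr an [ExpressionMatrix-class] (`log_normalized`) of test
#'   samples.
#' @param testResponse named numeric response for the test samples.
#' @return A list with `r`, `p` (two-sided) and `n`.
#' @export
validateSignature <- function(sig, testExpr, testResponse) {
  y <- alignResponse(testExpr, testResponse)
  if (!is.null(sig@meta$trainIds)) {
    overlap <- intersect(sig@meta$trainIds, sampleIds(testExpr))
    if (length(overlap))
      stop("test samples overlap the training set: ",
           paste(head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  sc <- scoreSamples(sig, testExpr, frozenStats = TRUE)
  if (length(y) == 2) {
    warning("two-point Pearson correlation is degenerate (r = +/-1)")
    return(list(r = cor(sc$scores, y), p = NA_real_, n = 2L))
  }
  ct <- suppressWarnings(cor.test(sc$scores, y))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(y))
}

#' Derive a signature end-to-end
#'
#' Splits samples into training and testing sets, runs the stability
#' correlation filter on the training set, fits the penalized signature
#' on the candidates, and validates on the held-out set.
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized`) for the full
#'   derivation cohort.
#' @param response named numeric phospho response for all samples.
#' @param cfg a [derivationConfig()].
#' @return A [GeneSignature-class] whose `meta` records the candidate
#'   genes, selection frequencies, selected penalty, train/test ids and
#'   the held-out validation `validation_r` / `validation_p`.
#' @export
deriveSignature <- function(expr, response, cfg = derivationConfig()) {
  stopUnits(expr, "log_normalized", "deriveSignature")
  y <- alignResponse(expr, response)
  split <- splitTrainTest(sampleIds(expr), cfg$trainFraction,
                          seed = subSeed(cfg$seed, 17))
  trainExpr <- exprSubset(expr, samples = split$train)
  filt <- stabilityCorrelationFilter(trainExpr, y[split$train], cfg)
  if (!length(filt$candidates))
    stop("no candidate genes survive the stability correlation filter",
         call. = FALSE)
  sig <- fitPenalizedSignature(exprSubset(trainExpr,
                                          genes = filt$candidates),
                               y[split$train], cfg)
  sig@meta$frequency <- filt$frequency
  sig@meta$trainIds <- split$train
  sig@meta$testIds <- split$test
  val <- validateSignature(sig, exprSubset(expr, samples = split$test),
                           y[split$test])
  sig@meta$validation_r <- val$r
  sig@meta$validation_p <- val$p
  sig
}
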