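## Scoring cohorts against a signature, median dichotomization, gene-set
## median scores and effector/suppressor contrasts.

ScoreVector <- function(scores, signatureId = "score") {
  structure(list(sampleIds = names(scores), scores = unname(scores),
                 signatureId = signatureId),
            class = "ScoreVector")
}

#' @export
print.ScoreVector <- function(x, ...) {
  cat(sprintf("ScoreVector '%s': %d samples, range [%.3g, %.3g]\n",
              x$signatureId, length(x$scores), min(x$scores),
              max(x$scores)))
  invisible(x)
}

scoresNamed <- function(s) setNames(s$scores, s$sampleIds)

#' Score samples against a gene signature
#'
#' The per-sample score is the mean, over the signature genes available in
#' the matrix, of coefficient x z-normalized expression. By default genes
#' are z-normalized across the scored cohort; with `frozenStats = TRUE`
#' the training statistics stored in the signature's `meta` are applied
#' instead (train-to-test transfer). Signature genes absent from the
#' matrix are dropped with a warning; scoring fails only if none remain.
#'
#' @param sig a [GeneSignature-class].
#' @param expr an [ExpressionMatrix-class] (`log_normalized`).
#' @param frozenStats use `sig@meta$center` / `sig@meta$scale` for the
#'   z-transform instead of cohort statistics.
#' @return A `ScoreVector` (list with `sampleIds`, `scores`,
#'   `signatureId`).
#' @examples
#' m <- ExpressionMatrix(matrix(c(1, 2, 3, 6, 5, 4), 2, 3, byrow = TRUE,
#'        dimnames = list(c("gA", "gB"), c("s1", "s2", "s3"))),
#'        "log_normalized")
#' sig <- GeneSignature(c("gA", "gB"), c(1, -1))
#' scoreSamples(sig, m)$scores
#' @export
scoreSamples <- function(sig, expr, frozenStats = FALSE) {
  stopUnits(expr, "log_normalized", "scoreSamples")
  present <- intersect(geneIds(sig), geneIds(expr))
  if (!length(present))
    stop("no signature genes present in the expression matrix",
         call. = FALSE)
  missing <- setdiff(geneIds(sig), present)
  if (length(missing))
    warning(sprintf("%d signature gene(s) absent from matrix: %s",
                    length(missing), paste(head(missing, 5),
                                           collapse = ", ")))
  v <- exprValues(expr)[present, , drop = FALSE]
  if (frozenStats) {
    if (is.null(sig@meta$center) || is.null(sig@meta$scale))
      stop("signature carries no frozen z-statistics", call. = FALSE)
    z <- zApply(v, sig@meta$center[present], sig@meta$scale[present])
  } else {
    scl <- apply(v, 1, sd)
    if (any(scl == 0))
      stop("zero-variance signature gene(s) in scored cohort: ",
           paste(rownames(v)[scl == 0], collapse = ", "), call. = FALSE)
    z <- zApply(v, rowMeans(v), scl)
  }
  beta <- sigCoefficients(sig)[present]
  ScoreVector(colMeans(beta * z),
              signatureId = if (!is.null(sig@meta$label)) sig@meta$label
                            else "signature")
}

#' Dichotomize scores at the cohort median
#'
#' Samples at or below the median score are labeled `low`, the rest
#' `high` (ties at the median go to `low`).
#'
#' @param s a `ScoreVector` with at least 2 samples.
#' @return A `GroupLabels` list: `sampleIds`, `label` (factor low/high)
#'   and `cutoff` (the median).
#' @export
dichotomizeByMedian <- function(s) {
  x <- scoresNamed(s)
  if (length(x) < 2) stop("need at least 2 samples to dichotomize",
                          call. = FALSE)
  if (length(unique(x)) == 1)
    stop("all scores identical; no median split possible", call. = FALSE)
  med <- median(x)
  structure(list(sampleIds = names(x),
                 label = factor(ifelse(x <= med, "low", "high"),
                                levels = c("low", "high")),
                 cutoff = med),
            class = "GroupLabels")
}

#' Gene-set median score
#'
#' Per sample, the median expression of the set's genes — the simple
#' single-sample score used for immune and stromal gene lists (e.g.
#' CIBERSORT-derived Treg and CD8 T-cell lists summarised by their median
#' expression).
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized` or
#'   `z_scored`).
#' @param geneSet character vector of gene ids; at least one must be
#'   present.
#' @param setName provenance string for the resulting score.
#' @return A `ScoreVector`.
#' @export
geneSetMedianScore <- function(expr, geneSet, setName = "gene_set") {
  if (exprUnits(expr) == "raw_counts")
    stop("geneSetMedianScore expects log-normalized or z-scored input",
         call. = FALSE)
  present <- intersect(geneSet, geneIds(expr))
  if (!length(present))
    stop("no genes of the set are present in the matrix", call. = FALSE)
  v <- exprValues(expr)[present, , drop = FALSE]
  ScoreVector(apply(v, 2, median), signatureId = setName)
}

#' Effector/suppressor score contrast
#'
#' For non-negative abundance-like scores, the elementwise ratio
#' `effector / (suppressor + epsilon)`; for log-scale scores
#' (`mode = "log"`), the difference `effector - suppressor`.
#'
#' @param effector,suppressor `ScoreVector`s over the same samples.
#' @param epsilon positive guard added to the denominator in abundance
#'   mode.
#' @param mode `"abundance"` (ratio) or `"log"` (difference).
#' @return A `ScoreVector`.
#' @export
effectorSuppressorRatio <- function(effector, suppressor, epsilon = 0.01,
                                    mode = c("abundance", "log")) {
  mode <- match.arg(mode)
  if (!identical(effector$sampleIds, suppressor$sampleIds))
    stop("effector and suppressor sample ids are misaligned",
         call. = FALSE)
  if (mode == "abundance" && (!is.numeric(epsilon) || epsilon < 0))
    stop("epsilon must be >= 0", call. = FALSE)
  out <- if (mode == "abundance")
    effector$scores / (suppressor$scores + epsilon)
  else effector$scores - suppressor$scores
  ScoreVector(setNames(out, effector$sampleIds),
              signatureId = sprintf("%s_vs_%s", effector$signatureId,
                                    suppressor$signatureId))
}
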