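## Centroid-score TNBC molecular subtyping with BL2 reassignment, and a
## transparent two-axis tumor-immune-microenvironment (TIME) classifier.

#' Compute per-subtype centroid scores
#'
#' Each gene is centered and scaled across samples (zero-variance genes
#' contribute z = 0); the score of a sample for a subtype is the mean z
#' of the subtype's positively associated genes minus the mean z of its
#' negatively associated genes (0 when the negative list is empty or
#' absent from the matrix).
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized`).
#' @param sets a [SubtypeGeneSets-class]; every subtype must have at
#'   least one positive gene present in `expr`.
#' @return A numeric matrix, samples in rows, one column per subtype.
#' @export
computeSubtypeScores <- function(expr, sets) {
  stopUnits(expr, "log_normalized", "computeSubtypeScores")
  v <- exprValues(expr)
  scl <- apply(v, 1, sd)
  z <- (v - rowMeans(v)) / ifelse(scl > 0, scl, 1)
  z[scl == 0, ] <- 0
  setsL <- subtypeSets(sets)
  out <- matrix(NA_real_, ncol(v), length(setsL),
                dimnames = list(colnames(v), names(setsL)))
  for (s in names(setsL)) {
    up <- intersect(setsL[[s]]$up, rownames(z))
    if (!length(up))
      stop(sprintf("subtype %s has no positive genes present in the matrix",
                   s), call. = FALSE)
    dn <- intersect(setsL[[s]]$dn, rownames(z))
    upMean <- colMeans(z[up, , drop = FALSE])
    dnMean <- if (length(dn)) colMeans(z[dn, , drop = FALSE]) else 0
    out[, s] <- upMean - dnMean
  }
  out
}

#' Assign molecular subtypes from centroid scores
#'
#' The subtype with the highest score wins; samples whose winner is the
#' unstable BL2 subtype are reassigned to their second-highest subtype,
#' and BL1 is reported under the stable five-subtype label `BL`. Exact
#' score ties are broken by a fixed subtype order (BL1, IM, M, LAR, MSL,
#' BL2 last) and flagged. Every sample receives exactly one of the five
#' calls.
#'
#' @param scores samples x subtypes matrix from [computeSubtypeScores()];
#'   all six subtype columns must be present.
#' @return A `data.frame` with `sample_id`, `call` (BL/IM/M/LAR/MSL),
#'   `raw_argmax` (the six-way winner), `reassigned` (TRUE iff the winner
#'   was BL2) and `tied` (TRUE if the governing maximum was an exact
#'   tie).
#' @export
assignSubtype <- function(scores) {
  if (!all(SUBTYPE_NAMES %in% colnames(scores)))
    stop("scores must contain all six subtype columns: ",
         paste(setdiff(SUBTYPE_NAMES, colnames(scores)), collapse = ", "),
         call. = FALSE)
  scores <- scores[, SUBTYPE_NAMES, drop = FALSE]
  tiePref <- match(colnames(scores), SUBTYPE_TIE_ORDER)
  n <- nrow(scores)
  call <- raw <- character(n)
  reassigned <- tied <- logical(n)
  for (i in seq_len(n)) {
    sc <- scores[i, ]
    ord <- order(-sc, tiePref)
    raw[i] <- colnames(scores)[ord[1]]
    if (raw[i] == "BL2") {
      reassigned[i] <- TRUE
      winner <- colnames(scores)[ord[2]]
      tied[i] <- sum(sc == sc[ord[2]]) > 1
    } else {
      winner <- raw[i]
      tied[i] <- sum(sc == sc[ord[1]]) > 1
    }
    call[i] <- if (winner == "BL1") "BL" else winner
  }
  data.frame(sample_id = rownames(scores), call = call, raw_argmax = raw,
             reassigned = reassigned, tied = tied,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' TIME classifier configuration
#'
#' @param immuneSet,stromalSet character vectors of gene ids scored by
#'   [geneSetMedianScore()] on z-scored expression.
#' @param immuneThreshold,stromalThreshold decision thresholds on the
#'   median-z scale (default 0, the cohort centre).
#' @param delta half-width of the ambiguity band around each governing
#'   threshold; samples inside the band are left unclassified.
#' @return A list of class `TimeConfig`.
#' @export
timeConfig <- function(immuneSet, stromalSet, immuneThreshold = 0,
                       stromalThreshold = 0, delta = 0.25) {
  if (missing(immuneSet) || missing(stromalSet) ||
      !length(immuneSet) || !length(stromalSet))
    stop("timeConfig requires non-empty immune and stromal gene sets",
         call. = FALSE)
  stopifnot(delta >= 0)
  structure(list(immuneSet = immuneSet, stromalSet = stromalSet,
                 immuneThreshold = immuneThreshold,
                 stromalThreshold = stromalThreshold, delta = delta),
            class = "TimeConfig")
}

#' Classify tumor immune microenvironment (TIME) patterns
#'
#' A transparent two-axis thresholding scheme over an immune and a
#' stromal gene-set median score (computed on gene-wise z-scored
#' expression): immune score above its threshold gives fully inflamed
#' (FI); immune below with stromal above gives stroma restricted (SR);
#' both below gives margin restricted (MR). Samples whose governing score
#' falls inside the `delta` ambiguity band are left unclassified.
#'
#' @param expr an [ExpressionMatrix-class] (`log_normalized`).
#' @param cfg a [timeConfig()].
#' @return A named factor with levels FI, SR, MR, unclassified.
#' @export
classifyTime <- function(expr, cfg) {
  stopifnot(inherits(cfg, "TimeConfig"))
  zres <- zNormalizeGenes(expr)
  imm <- scoresNamed(geneSetMedianScore(zres$expression, cfg$immuneSet,
                                        "immune"))
  str <- scoresNamed(geneSetMedianScore(zres$expression, cfg$stromalSet,
                                        "stromal"))
  out <- rep("unclassified", length(imm))
  hiImm <- imm > cfg$immuneThreshold + cfg$delta
  loImm <- imm < cfg$immuneThreshold - cfg$delta
  hiStr <- str > cfg$stromalThreshold + cfg$delta
  loStr <- str < cfg$stromalThreshold - cfg$delta
  out[hiImm] <- "FI"
  out[loImm & hiStr] <- "SR"
  out[loImm & loStr] <- "MR"
  factor(setNames(out, names(imm)),
         levels = c("FI", "SR", "MR", "unclassified"))
}
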