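## Sample/gene filtering and normalization applied ahead of signature
## derivation and scoring. The pipeline default order is samples first,
## then genes.

#' Filter samples by total mapped reads
#'
#' Drops samples whose column sum (the proxy for reads mapped to the
#' transcriptome) falls below `threshold`. FFPE-derived libraries commonly
#' fail this check; the reference analysis uses 200,000 reads.
#'
#' @param m an [ExpressionMatrix-class] with `raw_counts` units.
#' @param threshold minimum column sum to retain a sample.
#' @return A list: `expression` (filtered matrix, sample order preserved)
#'   and `excluded` (character vector of dropped sample ids).
#' @export
filterSamplesByMappedReads <- function(m, threshold = 200000) {
  stopUnits(m, "raw_counts", "filterSamplesByMappedReads")
  keep <- colSums(exprValues(m)) >= threshold
  if (!any(keep))
    stop("all samples fall below the mapped-read threshold; no samples left",
         call. = FALSE)
  list(expression = exprSubset(m, samples = which(keep)),
       excluded = sampleIds(m)[!keep])
}

#' Filter genes by expression prevalence
#'
#' Retains genes expressed (count > 0) in at least
#' `ceiling(minFraction * nSamples)` samples. The reference analysis keeps
#' genes expressed in at least 70% of samples.
#'
#' @param m an [ExpressionMatrix-class] with `raw_counts` units.
#' @param minFraction minimum fraction of samples with a non-zero count,
#'   in (0, 1].
#' @return A list: `expression` (filtered matrix, gene order preserved)
#'   and `excluded` (dropped gene ids).
#' @export
filterGenesByPrevalence <- function(m, minFraction = 0.7) {
  stopUnits(m, "raw_counts", "filterGenesByPrevalence")
  if (!is.numeric(minFraction) || minFraction <= 0 || minFraction > 1)
    stop("minFraction must lie in (0, 1]", call. = FALSE)
  need <- ceiling(minFraction * ncol(exprValues(m)))
  keep <- rowSums(exprValues(m) > 0) >= need
  list(expression = exprSubset(m, genes = which(keep)),
       excluded = geneIds(m)[!keep])
}

#' Log-normalize a count matrix
#'
#' Converts counts to log2 counts-per-million: per sample, counts are
#' scaled to sum to one million, then `log2(cpm + pseudocount)` is taken.
#' Monotone in the input counts within each sample and invariant to
#' per-sample library-size rescaling.
#'
#' @param m an [ExpressionMatrix-class] with `raw_counts` units.
#' @param pseudocount positive offset added before the log (default 1).
#' @return An [ExpressionMatrix-class] with `log_normalized` units.
#' @export
logNormalize <- function(m, pseudocount = 1) {
  stopUnits(m, "raw_counts", "logNormalize")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0", call. = FALSE)
  v <- exprValues(m)
  libs <- colSums(v)
  if (any(libs == 0))
    stop("sample(s) with zero total counts cannot be CPM-normalized: ",
         paste(colnames(v)[libs == 0], collapse = ", "), call. = FALSE)
  cpm <- sweep(v, 2, libs, "/") * 1e6
  ExpressionMatrix(log2(cpm + pseudocount), "log_normalized")
}

#' Restrict matrices to a common gene universe
#'
#' Derivation against external cohorts is performed on the genes present
#' in every dataset; this helper computes that intersection and subsets
#' each matrix to it (row order taken from the first matrix).
#'
#' @param ... two or more [ExpressionMatrix-class] objects.
#' @return A list of matrices, each restricted to the shared genes in a
#'   common order.
#' @export
intersectGeneUniverse <- function(...) {
  mats <- list(...)
  if (length(mats) < 2) stop("need at least two matrices", call. = FALSE)
  common <- Reduce(intersect, lapply(mats, geneIds))
  if (!length(common))
    stop("no genes shared across all matrices", call. = FALSE)
  lapply(mats, exprSubset, genes = common)
}

#' z-normalize genes across samples
#'
#' Centers each gene row and scales it to unit variance using the
#' unbiased (n-1) standard deviation. Zero-variance rows cannot be scaled;
#' they are excluded from the output and reported.
#'
#' @param m an [ExpressionMatrix-class] with `log_normalized` units.
#' @return A list: `expression` (a `z_scored` [ExpressionMatrix-class])
#'   and `zeroVariance` (gene ids excluded for having no variance).
#' @export
zNormalizeGenes <- function(m) {
  stopUnits(m, "log_normalized", "zNormalizeGenes")
  v <- exprValues(m)
  if (ncol(v) < 2)
    stop("z-normalization needs at least 2 samples", call. = FALSE)
  sds <- apply(v, 1, sd)
  flat <- sds == 0 | !is.finite(sds)
  z <- (v[!flat, , drop = FALSE] - rowMeans(v[!flat, , drop = FALSE])) /
    sds[!flat]
  list(expression = ExpressionMatrix(z, "z_scored"),
       zeroVariance = rownames(v)[flat])
}
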