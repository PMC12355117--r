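#' @import methods
#' @importFrom stats approx coef cor cor.test median model.matrix p.adjust
#'   pchisq pnorm predict qnorm quantile rbeta rbinom rexp rnorm rpois runif
#'   sd setNames uniroot var
#' @importFrom utils head read.csv write.csv
NULL

EXPR_UNITS <- c("raw_counts", "log_normalized", "z_scored")

#' Gene-by-sample expression matrix with a units tag
#'
#' A thin container for a numeric genes x samples matrix. Gene and sample
#' identifiers live in the matrix dimnames and must be unique; the `units`
#' tag records where the matrix sits in the processing chain (`raw_counts`,
#' `log_normalized` or `z_scored`) so that operations can refuse input at
#' the wrong stage.
#'
#' @slot values numeric matrix, genes in rows, samples in columns, with
#'   complete dimnames.
#' @slot units character(1), one of `"raw_counts"`, `"log_normalized"`,
#'   `"z_scored"`.
#'
#' @seealso [ExpressionMatrix()] constructor, [geneIds()], [sampleIds()],
#'   [exprValues()], [exprUnits()]
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", units = "character"))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msgs <- c(msgs, "values must carry gene (row) and sample (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msgs <- c(msgs, "duplicate gene ids")
    if (anyDuplicated(colnames(v)))
      msgs <- c(msgs, "duplicate sample ids")
  }
  if (length(object@units) != 1L || !object@units %in% EXPR_UNITS)
    msgs <- c(msgs, sprintf("units must be one of: %s",
                            paste(EXPR_UNITS, collapse = ", ")))
  else if (object@units == "raw_counts" && any(v < 0))
    msgs <- c(msgs, "raw_counts must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with dimnames.
#' @param units one of `"raw_counts"`, `"log_normalized"`, `"z_scored"`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' ExpressionMatrix(m, "raw_counts")
#' @export
ExpressionMatrix <- function(values, units = c("raw_counts",
                                               "log_normalized",
                                               "z_scored")) {
  units <- match.arg(units)
  new("ExpressionMatrix", values = as.matrix(values), units = units)
}

#' A gene expression signature with derivation metadata
#'
#' Ordered gene identifiers with non-zero regression coefficients plus the
#' metadata produced during derivation (configuration, candidate list,
#' selected penalty, training z-statistics, validation correlation).
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot coefficients numeric vector aligned to `geneIds`; never zero.
#' @slot meta list of derivation metadata (free-form; populated by
#'   [deriveSignature()]).
#' @export
setClass("GeneSignature",
  representation(geneIds = "character", coefficients = "numeric",
                 meta = "list"))

setValidity("GeneSignature", function(object) {
  msgs <- character()
  if (length(object@geneIds) != length(object@coefficients))
    msgs <- c(msgs, "geneIds and coefficients lengths differ")
  if (anyDuplicated(object@geneIds))
    msgs <- c(msgs, "duplicate gene ids in signature")
  if (length(object@coefficients) &&
      (any(!is.finite(object@coefficients)) || any(object@coefficients == 0)))
    msgs <- c(msgs, "coefficients must be finite and non-zero")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSignature
#'
#' @param geneIds character vector of gene ids.
#' @param coefficients numeric vector aligned to `geneIds`; zero entries are
#'   not allowed (drop them before constructing).
#' @param meta optional list of derivation metadata.
#' @return A [GeneSignature-class] object.
#' @export
GeneSignature <- function(geneIds, coefficients, meta = list()) {
  new("GeneSignature", geneIds = as.character(geneIds),
      coefficients = as.numeric(coefficients), meta = meta)
}

SUBTYPE_NAMES <- c("BL1", "BL2", "IM", "M", "LAR", "MSL")
## fixed order used to break exact score ties (BL2 last, never favoured)
SUBTYPE_TIE_ORDER <- c("BL1", "IM", "M", "LAR", "MSL", "BL2")

#' Per-subtype positive/negative marker gene sets
#'
#' For each TNBC molecular subtype (BL1, BL2, IM, M, LAR, MSL) a list with
#' components `up` (genes positively associated) and `dn` (genes negatively
#' associated). Within a subtype the two lists are disjoint and `up` is
#' non-empty.
#'
#' @slot sets named list, one element per subtype, each a
#'   `list(up = character, dn = character)`.
#' @export
setClass("SubtypeGeneSets", representation(sets = "list"))

setValidity("SubtypeGeneSets", function(object) {
  msgs <- character()
  nm <- names(object@sets)
  if (is.null(nm) || !all(nzchar(nm)))
    msgs <- c(msgs, "sets must be named by subtype")
  for (s in nm) {
    el <- object@sets[[s]]
    if (!is.list(el) || !all(c("up", "dn") %in% names(el))) {
      msgs <- c(msgs, sprintf("subtype %s lacks up/dn components", s))
      next
    }
    if (length(el$up) < 1L)
      msgs <- c(msgs, sprintf("subtype %s has empty positive gene list", s))
    if (length(intersect(el$up, el$dn)))
      msgs <- c(msgs, sprintf("subtype %s up/dn lists overlap", s))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct SubtypeGeneSets
#'
#' @param sets named list of `list(up=, dn=)` character vectors, one per
#'   subtype.
#' @return A [SubtypeGeneSets-class] object.
#' @export
SubtypeGeneSets <- function(sets) new("SubtypeGeneSets", sets = sets)
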