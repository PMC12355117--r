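#' Accessors for package classes
#'
#' `geneIds()` and `sampleIds()` return identifier vectors; `exprValues()`
#' the underlying numeric matrix; `exprUnits()` the units tag;
#' `sigCoefficients()` a named coefficient vector; `subtypeSets()` the
#' named list of marker sets.
#'
#' @param x an [ExpressionMatrix-class], [GeneSignature-class] or
#'   [SubtypeGeneSets-class] object, as appropriate.
#' @return See individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("exprUnits", function(x) standardGeneric("exprUnits"))
#' @rdname accessors
#' @export
setGeneric("sigCoefficients", function(x) standardGeneric("sigCoefficients"))
#' @rdname accessors
#' @export
setGeneric("subtypeSets", function(x) standardGeneric("subtypeSets"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("exprUnits", "ExpressionMatrix", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneSignature", function(x) x@geneIds)
#' @rdname accessors
#' @export
setMethod("sigCoefficients", "GeneSignature",
          function(x) setNames(x@coefficients, x@geneIds))

#' @rdname accessors
#' @export
setMethod("subtypeSets", "SubtypeGeneSets", function(x) x@sets)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object@values), ncol(object@values), object@units))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature: %d genes\n", length(object@geneIds)))
  k <- min(5L, length(object@geneIds))
  if (k > 0L)
    cat("  ", paste(sprintf("%s(%.3g)", object@geneIds[seq_len(k)],
                            object@coefficients[seq_len(k)]),
                    collapse = " "),
        if (length(object@geneIds) > k) "..." else "", "\n")
  if (!is.null(object@meta$validation_r))
    cat(sprintf("  held-out validation r = %.3f\n",
                object@meta$validation_r))
})

setMethod("show", "SubtypeGeneSets", function(object) {
  sz <- vapply(object@sets, function(el)
    sprintf("%d+/%d-", length(el$up), length(el$dn)), character(1))
  cat("SubtypeGeneSets:",
      paste(sprintf("%s[%s]", names(sz), sz), collapse = " "), "\n")
})

## shared helper: subset an ExpressionMatrix preserving class/units
exprSubset <- function(m, genes = NULL, samples = NULL) {
  v <- exprValues(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  ExpressionMatrix(v, exprUnits(m))
}

stopUnits <- function(m, expected, what) {
  if (exprUnits(m) != expected)
    stop(sprintf("%s expects units '%s', got '%s'", what, expected,
                 exprUnits(m)), call. = FALSE)
}
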