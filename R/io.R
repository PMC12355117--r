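## Plain-text serialization: gene-by-sample TSV with a units pragma,
## GMT gene sets, clinical CSV, signature TSV + JSON sidecar.

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample ids whose first field names the gene-id
#' column, one row per gene. A leading pragma line `#units=<units>` sets
#' the units tag; otherwise the `units` argument is used. Ragged rows,
#' duplicate gene ids, non-numeric cells and empty files are rejected
#' with informative errors.
#'
#' @param path TSV file path.
#' @param units fallback units when the file carries no pragma.
#' @return An [ExpressionMatrix-class].
#' @export
readExpression <- function(path, units = "raw_counts") {
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path, call. = FALSE)
  if (startsWith(lines[1], "#units=")) {
    units <- sub("^#units=", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) < 2)
    stop("expression file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != nf[1]))
    stop(sprintf("ragged expression file: line %d has %d fields, expected %d",
                 which(nf != nf[1])[1] + 1L, nf[nf != nf[1]][1], nf[1]),
         call. = FALSE)
  samples <- fields[[1]][-1]
  rows <- fields[-1]
  gids <- vapply(rows, `[[`, character(1), 1L)
  dup <- gids[duplicated(gids)]
  if (length(dup))
    stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(rows, function(f) as.numeric(f[-1]), numeric(length(samples))))
  vals <- matrix(vals, ncol = length(samples), byrow = TRUE,
                 dimnames = list(gids, samples))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1, any))[1]
    stop(sprintf("non-numeric cell(s) in gene row '%s'", gids[bad]),
         call. = FALSE)
  }
  ExpressionMatrix(vals, units)
}

#' Write a gene-by-sample expression TSV
#'
#' Emits a `#units=` pragma, a header row (first column `gene_id`) and
#' one row per gene; the exact inverse of [readExpression()].
#'
#' @param m an [ExpressionMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#units=", exprUnits(m)), con)
  writeLines(paste(c("gene_id", sampleIds(m)), collapse = "\t"), con)
  v <- exprValues(m)
  writeLines(paste(rownames(v),
                   apply(v, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a set name, a description and tab-separated
#' gene ids. Gene order is preserved; duplicate genes within a set are
#' collapsed with a warning; a line with fewer than 3 fields is a parse
#' error reported with its line number.
#'
#' @param path GMT file path.
#' @return A named list of character vectors; set descriptions in
#'   `attr(, "description")`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT parse error: line %d has %d field(s), need >= 3",
                 short[1], lengths(fields)[short[1]]), call. = FALSE)
  sets <- list(); descs <- character()
  for (f in fields) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("duplicate gene(s) in set '%s'; collapsed", f[1]))
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
    descs[f[1]] <- f[2]
  }
  attr(sets, "description") <- descs
  sets
}

#' Write gene sets to a GMT file
#'
#' A [SubtypeGeneSets-class] is written using the `<SUBTYPE>_UP` /
#' `<SUBTYPE>_DN` naming convention; a plain named list is written as-is.
#'
#' @param sets a named list of character vectors or a
#'   [SubtypeGeneSets-class].
#' @param path output file path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "phosphoSig") {
  if (is(sets, "SubtypeGeneSets")) {
    lst <- list()
    for (s in names(subtypeSets(sets))) {
      lst[[paste0(s, "_UP")]] <- subtypeSets(sets)[[s]]$up
      lst[[paste0(s, "_DN")]] <- subtypeSets(sets)[[s]]$dn
    }
    sets <- lst
  }
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Assemble SubtypeGeneSets from GMT sets
#'
#' Interprets `<SUBTYPE>_UP` / `<SUBTYPE>_DN` set names (e.g. `IM_UP`)
#' as the positive/negative marker lists of each subtype.
#'
#' @param gmt a named list as returned by [readGMT()].
#' @return A [SubtypeGeneSets-class].
#' @export
gmtToSubtypeGeneSets <- function(gmt) {
  sets <- list()
  for (s in SUBTYPE_NAMES) {
    up <- gmt[[paste0(s, "_UP")]]
    if (is.null(up))
      stop(sprintf("GMT lacks set %s_UP", s), call. = FALSE)
    dn <- gmt[[paste0(s, "_DN")]]
    sets[[s]] <- list(up = up, dn = if (is.null(dn)) character(0) else dn)
  }
  SubtypeGeneSets(sets)
}

#' Write / read a clinical cohort CSV
#'
#' @param cohort a `ClinicalCohort` data frame.
#' @param path CSV file path.
#' @return `writeClinical`: `path` invisibly; `readClinical`: a
#'   `ClinicalCohort` data frame.
#' @export
writeClinical <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeClinical
#' @export
readClinical <- function(path) {
  structure(read.csv(path, stringsAsFactors = FALSE),
            class = c("ClinicalCohort", "data.frame"))
}

#' Serialize / deserialize a gene signature
#'
#' The signature is written as a two-column TSV (`gene_id`,
#' `coefficient`) with a JSON metadata sidecar at `<path>.json` (selected
#' penalty, validation correlation, frozen z-statistics).
#'
#' @param sig a [GeneSignature-class].
#' @param path TSV file path.
#' @return `writeSignature`: `path` invisibly; `readSignature`: a
#'   [GeneSignature-class].
#' @export
writeSignature <- function(sig, path) {
  writeLines(c("gene_id\tcoefficient",
               paste(geneIds(sig), format(sig@coefficients, digits = 17),
                     sep = "\t")), path)
  meta <- sig@meta
  meta$config <- NULL                 # configs carry their own classes
  for (f in c("center", "scale", "frequency"))
    if (!is.null(meta[[f]])) meta[[f]] <- as.list(meta[[f]])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
  tab <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  meta <- list()
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (f in c("center", "scale"))
      if (!is.null(meta[[f]])) meta[[f]] <- unlist(meta[[f]])
  }
  GeneSignature(tab$gene_id, tab$coefficient, meta = meta)
}
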