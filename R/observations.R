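#' Read a long-format observation table
#'
#' Reads a delimited text file with header columns
#' \code{cell,clone,mutation,vaf,score} and returns a validated
#' [CloneObservations-class] object. Rows violating the invariants (VAF
#' outside \[0, 1\], non-numeric or non-finite values) are rejected with an
#' error citing the offending line; they are never silently dropped.
#'
#' @param path path to a CSV or TSV file.
#' @param dialect \code{"auto"} picks the delimiter from the file
#'   extension (\code{.tsv}/\code{.tab} means tab, anything else comma);
#'   \code{"csv"} and \code{"tsv"} override.
#' @param groupBy \code{"clone"} pools all cells of a clone into one group
#'   sharing (pi, a, b); \code{"cell-clone"} gives every (cell, clone)
#'   pair its own group.
#' @return A [CloneObservations-class] object.
#' @export
readObservations <- function(path, dialect = c("auto", "csv", "tsv"),
                             groupBy = c("clone", "cell-clone")) {
  dialect <- match.arg(dialect)
  groupBy <- match.arg(groupBy)
  if (!file.exists(path)) .stopValidation(paste("file not found:", path))
  sep <- .tableSep(path, dialect)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           quote = "\"", comment.char = "")
  need <- c("cell", "clone", "mutation", "vaf", "score")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    .stopValidation(paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")))
  if (nrow(raw) == 0) .stopValidation("no observations")
  # header is line 1, so data row i sits on line i + 1
  vaf <- suppressWarnings(as.numeric(raw$vaf))
  bad <- which(is.na(vaf) | vaf < 0 | vaf > 1)
  if (length(bad) > 0)
    .stopValidation(paste0("invalid vaf (must be numeric in [0, 1]) on line ",
                           bad[1] + 1, ": '", raw$vaf[bad[1]], "'"))
  score <- suppressWarnings(as.numeric(raw$score))
  badS <- which(!is.finite(score))
  if (length(badS) > 0)
    .stopValidation(paste0("invalid score (must be finite) on line ",
                           badS[1] + 1, ": '", raw$score[badS[1]], "'"))
  .makeObservations(cell = raw$cell, clone = raw$clone,
                    mutation = raw$mutation, vaf = vaf, score = score,
                    groupBy = groupBy)
}

.tableSep <- function(path, dialect) {
  if (dialect == "csv") return(",")
  if (dialect == "tsv") return("\t")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "tab", "txt")) "\t" else ","
}

.makeObservations <- function(cell, clone, mutation, vaf, score,
                              groupBy = "clone") {
  group <- if (groupBy == "cell-clone") paste(cell, clone, sep = ":")
           else as.character(clone)
  rec <- data.frame(cell = as.character(cell), group = group,
                    clone = as.character(clone),
                    mutation = as.character(mutation),
                    vaf = vaf, score = score, stringsAsFactors = FALSE)
  key <- paste(rec$cell, rec$clone, rec$mutation, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    .stopValidation(paste0("duplicate (cell, clone, mutation) triple: ",
                           gsub("\r", "/", d, fixed = TRUE)))
  }
  new("CloneObservations", records = rec)
}

#' Assemble observations from a VAF matrix and per-cell tables
#'
#' Matrix-mode input: a cell-by-mutation VAF matrix plus a cell-to-clone
#' assignment and a per-cell scalar disease score. The cell's single score
#' is replicated onto each of its retained mutation records, matching the
#' per-(cell, clone, mutation) indexing of the likelihood while using the
#' only phenotype available per cell. By default only records with VAF > 0
#' are kept; \code{retainZeros = TRUE} keeps zero-VAF entries too.
#'
#' @param vafMatrix numeric matrix (or \pkg{Matrix} sparse matrix) with
#'   cells as rows and mutations as columns, dimnames required.
#' @param cloneMap data.frame with columns \code{cell}, \code{clone} (or a
#'   named character vector).
#' @param scoreMap data.frame with columns \code{cell}, \code{score} (or a
#'   named numeric vector).
#' @param retainZeros keep records whose VAF is exactly 0.
#' @inheritParams readObservations
#' @return A [CloneObservations-class] object with one record per retained
#'   (cell, mutation) pair.
#' @export
assembleObservations <- function(vafMatrix, cloneMap, scoreMap,
                                 retainZeros = FALSE,
                                 groupBy = c("clone", "cell-clone")) {
  groupBy <- match.arg(groupBy)
  m <- as.matrix(vafMatrix)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    .stopValidation("vafMatrix needs cell rownames and mutation colnames")
  cloneMap <- .asMap(cloneMap, "clone")
  scoreMap <- .asMap(scoreMap, "score")
  cells <- rownames(m)
  missC <- setdiff(cells, names(cloneMap))
  missS <- setdiff(cells, names(scoreMap))
  if (length(missC) > 0 || length(missS) > 0)
    .stopValidation(paste0(
      "cells missing from ",
      if (length(missC) > 0) paste0("clone map: ",
                                    paste(missC, collapse = ", ")) else "",
      if (length(missC) > 0 && length(missS) > 0) "; " else "",
      if (length(missS) > 0) paste0("score map: ",
                                    paste(missS, collapse = ", ")) else ""))
  keep <- if (retainZeros) m >= 0 else m > 0
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0) .stopValidation("no observations")
  cell <- cells[idx[, 1]]
  .makeObservations(cell = cell,
                    clone = as.character(cloneMap[cell]),
                    mutation = colnames(m)[idx[, 2]],
                    vaf = m[idx], score = as.numeric(scoreMap[cell]),
                    groupBy = groupBy)
}

.asMap <- function(x, valueCol) {
  if (is.data.frame(x)) {
    if (!all(c("cell", valueCol) %in% names(x)))
      .stopValidation(paste0("mapping table needs columns cell, ", valueCol))
    stats::setNames(x[[valueCol]], x$cell)
  } else if (!is.null(names(x))) {
    x
  } else .stopValidation("mapping must be a data.frame or a named vector")
}

#' Read a VAF matrix from CSV/TSV or MatrixMarket
#'
#' CSV/TSV files are read with cells as rows (first column = cell id).
#' MatrixMarket (.mtx) files carry no dimnames, so companion files listing
#' the row (cell) and column (mutation) names are required.
#'
#' @param path matrix file.
#' @param cellsFile,mutationsFile one-name-per-line text files; required
#'   for \code{.mtx} input.
#' @return A base numeric matrix, cells as rows.
#' @export
readVafMatrix <- function(path, cellsFile = NULL, mutationsFile = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "mtx") {
    if (is.null(cellsFile) || is.null(mutationsFile))
      .stopValidation("mtx input needs cellsFile and mutationsFile")
    m <- as.matrix(Matrix::readMM(path))
    dimnames(m) <- list(readLines(cellsFile), readLines(mutationsFile))
    return(m)
  }
  sep <- .tableSep(path, "auto")
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}
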