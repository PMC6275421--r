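#' Read a delimited Ct table
#'
#' Parses a plain-text Ct table: the header row carries the sample IDs, the
#' first column the assay names (target miRNAs plus endogenous controls), and
#' every other cell a raw Ct cycle value or an undetermined marker. The
#' delimiter is chosen explicitly via \code{dialect}; it is never sniffed.
#'
#' @param path path to the delimited file.
#' @param dialect \code{"csv"} (comma) or \code{"tsv"} (tab).
#' @param missingMarkers tokens parsed as undetermined wells (stored as
#'   \code{NA}); defaults to those of \code{\link{DetectionPolicy}}.
#' @return A \linkS4class{CtExperiment}.
#' @seealso \code{\link{writeCtTable}}, \code{\link{detectNotExpressed}}
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("assay,S1,S2", "miR-107,21.9,22.3",
#'              "U6-2,30.1,Undetermined"), tf)
#' readCtTable(tf)
#' @export
readCtTable <- function(path, dialect = c("csv", "tsv"),
                        missingMarkers = DetectionPolicy()@missingMarkers) {
  CtExperiment(readDelimMatrix(path, dialect, missingMarkers))
}

# shared parser for assay-by-sample delimited matrices (Ct or delta-Ct)
readDelimMatrix <- function(path, dialect = c("csv", "tsv"), missingMarkers) {
  if (!file.exists(path))
    stop(sprintf("table not found: '%s'", path), call. = FALSE)
  sep <- sepForDialect(dialect)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character(0), quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("Ct table needs an assay column plus at least one sample column",
         call. = FALSE)
  assaysNm <- trimws(raw[[1L]])
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(assaysNm))
    stop(sprintf("duplicated assay name(s): %s",
                 paste(unique(assaysNm[duplicated(assaysNm)]), collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(samples))
    stop(sprintf("duplicated sample name(s): %s",
                 paste(unique(samples[duplicated(samples)]), collapse = ", ")),
         call. = FALSE)
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells[] <- trimws(cells)
  m <- matrix(NA_real_, nrow = nrow(cells), ncol = ncol(cells),
              dimnames = list(assaysNm, samples))
  isMissing <- matrix(cells %in% missingMarkers, nrow = nrow(cells))
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(!isMissing & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "cannot parse Ct cell '%s' at assay '%s' (row %d), sample '%s' (column %d)",
      cells[i, j], assaysNm[i], i, samples[j], j + 1L), call. = FALSE)
  }
  m[!isMissing] <- num[!isMissing]
  m
}

#' Write a Ct table as delimited text
#'
#' Inverse of \code{\link{readCtTable}}: writes full-precision Ct values so a
#' write-then-read round trip reproduces the matrix bit-exactly; undetermined
#' wells are serialized as \code{missingMarker}.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param path output path.
#' @param dialect \code{"csv"} or \code{"tsv"}.
#' @param missingMarker token written for undetermined wells.
#' @return \code{path}, invisibly.
#' @export
writeCtTable <- function(x, path, dialect = c("csv", "tsv"),
                         missingMarker = "Undetermined") {
  stopifnot(is(x, "CtExperiment"))
  sep <- sepForDialect(dialect)
  m <- ctMatrix(x)
  out <- cbind(assay = rownames(m),
               matrix(formatCtValue(m, missingMarker), nrow = nrow(m),
                      dimnames = dimnames(m)))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a twin sample sheet
#'
#' Parses a delimited sample sheet with columns \code{sample_id},
#' \code{pair_id}, \code{member} and \code{zygosity} into a validated
#' \linkS4class{TwinDesign}. Zygosity tokens \code{identical}/\code{MZ} and
#' \code{fraternal}/\code{DZ} are normalized to \code{monozygotic} and
#' \code{dizygotic}.
#'
#' @inheritParams readCtTable
#' @return A \linkS4class{TwinDesign}.
#' @export
readSampleSheet <- function(path, dialect = c("csv", "tsv")) {
  if (!file.exists(path))
    stop(sprintf("sample sheet not found: '%s'", path), call. = FALSE)
  sep <- sepForDialect(dialect)
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         colClasses = "character", check.names = FALSE,
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "pair_id", "member", "zygosity")
  missing <- setdiff(need, colnames(d))
  if (length(missing))
    stop(sprintf("sample sheet lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  TwinDesign(sampleId = d$sample_id, pairId = d$pair_id,
             member = d$member, zygosity = d$zygosity)
}

#' Write a twin sample sheet
#'
#' @param x a \linkS4class{TwinDesign}.
#' @inheritParams writeCtTable
#' @return \code{path}, invisibly.
#' @export
writeSampleSheet <- function(x, path, dialect = c("csv", "tsv")) {
  stopifnot(is(x, "TwinDesign"))
  d <- as.data.frame(designTable(x))
  colnames(d) <- c("sample_id", "pair_id", "member", "zygosity")
  utils::write.table(d, path, sep = sepForDialect(dialect), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Flag non-detected assays
#'
#' A well is non-detected when its Ct is undetermined or above the detection
#' limit \code{maxCt}; an assay is not expressed study-wide when every one of
#' its wells is non-detected (the situation of a target that never rises above
#' baseline in any sample). Lowering \code{maxCt} can only add flags, never
#' remove them.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param policy a \linkS4class{DetectionPolicy}.
#' @return A list with \code{assay} (named logical, study-wide not-expressed
#'   flag per assay) and \code{cell} (logical matrix of per-well flags).
#' @export
detectNotExpressed <- function(x, policy = DetectionPolicy()) {
  stopifnot(is(x, "CtExperiment"), is(policy, "DetectionPolicy"))
  m <- ctMatrix(x)
  cell <- is.na(m) | m > policy@maxCt
  list(assay = apply(cell, 1L, all), cell = cell)
}

#' Check a twin design against a Ct table
#'
#' Verifies that every sample of the design is a column of the Ct table.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param design a \linkS4class{TwinDesign}.
#' @return \code{TRUE}, invisibly; errors otherwise.
#' @export
validateDesign <- function(x, design) {
  stopifnot(is(x, "CtExperiment") || is(x, "ExpressionMatrix"),
            is(design, "TwinDesign"))
  missing <- setdiff(designTable(design)$sampleId, colnames(x))
  if (length(missing))
    stop(sprintf("design sample(s) absent from the Ct data: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
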