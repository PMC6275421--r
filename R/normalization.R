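#' Summarize endogenous controls per sample
#'
#' For each sample, the reference baseline is the arithmetic mean of the
#' non-missing Ct values of the named endogenous controls (U6-2 and SNORD48
#' by default). Averaging on the Ct scale is equivalent to a geometric mean of
#' the linear-scale abundances, the usual way stable small-RNA references are
#' combined. Samples in which only a subset of the controls amplified use the
#' controls that did, with a message; a sample with no usable control is an
#' error.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param controls names of the endogenous-control assays.
#' @return A \linkS4class{ReferenceBaseline}.
#' @examples
#' m <- matrix(c(21, 20, 22, 21.5, 20.5, 22.5), nrow = 3,
#'             dimnames = list(c("miR-107", "U6-2", "SNORD48"), c("S1", "S2")))
#' referenceBaseline(CtExperiment(m))
#' @export
referenceBaseline <- function(x, controls = c("U6-2", "SNORD48")) {
  stopifnot(is(x, "CtExperiment"))
  m <- ctMatrix(x)
  absent <- setdiff(controls, rownames(m))
  if (length(absent))
    stop(sprintf("control assay(s) not in the Ct table: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  ctrl <- m[controls, , drop = FALSE]
  usable <- apply(ctrl, 2L, function(v) controls[!is.na(v)], simplify = FALSE)
  dead <- names(usable)[lengths(usable) == 0L]
  if (length(dead))
    stop(sprintf("sample(s) with no usable endogenous control: %s",
                 paste(dead, collapse = ", ")), call. = FALSE)
  partial <- names(usable)[lengths(usable) < length(controls)]
  if (length(partial))
    message(sprintf("baseline from a reduced control set in sample(s): %s",
                    paste(partial, collapse = ", ")))
  baseline <- colMeans(ctrl, na.rm = TRUE)
  new("ReferenceBaseline", baseline = baseline, controlsUsed = usable,
      controlNames = as.character(controls))
}

#' Convert target Cts to delta-Ct relative expression
#'
#' Applies the comparative-Ct normalization: for every target miRNA and
#' sample, delta-Ct = mean reference Ct minus target Ct, so a larger value
#' means higher expression (each unit is a two-fold change). Endogenous
#' controls are dropped from the rows. Wells that are undetermined or above
#' the detection limit are flagged and carry no numeric value; a miRNA flagged
#' in every sample is marked not expressed study-wide.
#'
#' The per-sample baseline makes delta-Ct invariant to a constant cycle shift
#' of a whole sample (e.g. input-amount differences), which is the point of
#' reference-gene normalization.
#'
#' @param x a \linkS4class{CtExperiment}.
#' @param baseline a \linkS4class{ReferenceBaseline} covering every sample of
#'   \code{x}.
#' @param policy a \linkS4class{DetectionPolicy} supplying the detection
#'   limit.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
relativeExpression <- function(x, baseline, policy = DetectionPolicy()) {
  stopifnot(is(x, "CtExperiment"), is(baseline, "ReferenceBaseline"),
            is(policy, "DetectionPolicy"))
  m <- ctMatrix(x)
  b <- baselineValues(baseline)
  uncovered <- setdiff(colnames(m), names(b))
  if (length(uncovered))
    stop(sprintf("baseline lacks sample(s): %s",
                 paste(uncovered, collapse = ", ")), call. = FALSE)
  targets <- setdiff(rownames(m), baseline@controlNames)
  tm <- m[targets, , drop = FALSE]
  flagged <- is.na(tm) | tm > policy@maxCt
  dct <- sweep(-tm, 2L, b[colnames(m)], "+")
  dct[flagged] <- NA_real_
  se <- SummarizedExperiment(
    assays = SimpleList(dct = dct, flagged = flagged),
    rowData = DataFrame(notExpressed = apply(flagged, 1L, all),
                        row.names = targets))
  metadata(se)$controls <- baseline@controlNames
  metadata(se)$maxCt <- policy@maxCt
  new("ExpressionMatrix", se)
}

#' Write / read a delta-Ct expression matrix
#'
#' Same layout as the Ct table (header = sample IDs, first column = miRNA);
#' flagged (not-expressed) cells are serialized as \code{"NE"}.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @inheritParams writeCtTable
#' @return \code{path}, invisibly (writer); an \linkS4class{ExpressionMatrix}
#'   (reader).
#' @export
writeExpressionMatrix <- function(x, path, dialect = c("csv", "tsv")) {
  stopifnot(is(x, "ExpressionMatrix"))
  d <- dctMatrix(x)
  out <- cbind(assay = rownames(d),
               matrix(formatCtValue(d, "NE"), nrow = nrow(d),
                      dimnames = dimnames(d)))
  utils::write.table(out, path, sep = sepForDialect(dialect), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeExpressionMatrix
#' @export
readExpressionMatrix <- function(path, dialect = c("csv", "tsv")) {
  d <- readDelimMatrix(path, dialect, missingMarkers = "NE")
  flagged <- is.na(d)
  se <- SummarizedExperiment(
    assays = SimpleList(dct = d, flagged = flagged),
    rowData = DataFrame(notExpressed = apply(flagged, 1L, all),
                        row.names = rownames(d)))
  new("ExpressionMatrix", se)
}
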