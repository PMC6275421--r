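#' Accessors for twinMiR classes
#'
#' Small accessor layer over the S4 slots: \code{ctMatrix} returns the raw Ct
#' matrix of a \linkS4class{CtExperiment}; \code{dctMatrix} and
#' \code{flaggedMatrix} the delta-Ct and flag assays of an
#' \linkS4class{ExpressionMatrix}; \code{notExpressed} the study-wide
#' not-expressed row flags; \code{designTable} the sample-to-pair map of a
#' \linkS4class{TwinDesign}; \code{baselineValues} and \code{controlsUsed} the
#' per-sample reference summary; \code{h2Raw}, \code{h2Clamped} and
#' \code{environmentShare} the Falconer partition; \code{h2Expected},
#' \code{trueDct}, \code{ctTable} and \code{twinDesign} the components of a
#' \linkS4class{SimulatedStudy}.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
ctMatrix <- function(x) {
  stopifnot(is(x, "CtExperiment"))
  assay(x, "ct")
}

#' @rdname accessors
#' @export
dctMatrix <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  assay(x, "dct")
}

#' @rdname accessors
#' @export
flaggedMatrix <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  assay(x, "flagged")
}

#' @rdname accessors
#' @export
notExpressed <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  structure(rowData(x)$notExpressed, names = rownames(x))
}

#' @rdname accessors
#' @export
designTable <- function(x) {
  stopifnot(is(x, "TwinDesign"))
  x@design
}

#' @rdname accessors
#' @export
baselineValues <- function(x) {
  stopifnot(is(x, "ReferenceBaseline"))
  x@baseline
}

#' @rdname accessors
#' @export
controlsUsed <- function(x) {
  stopifnot(is(x, "ReferenceBaseline"))
  x@controlsUsed
}

#' @rdname accessors
#' @export
h2Raw <- function(x) {
  stopifnot(is(x, "HeritabilityEstimate"))
  x@h2Raw
}

#' @rdname accessors
#' @export
h2Clamped <- function(x) {
  stopifnot(is(x, "HeritabilityEstimate"))
  x@h2Clamped
}

#' @rdname accessors
#' @export
environmentShare <- function(x) {
  stopifnot(is(x, "HeritabilityEstimate"))
  x@environmentShare
}

#' @rdname accessors
#' @export
h2Expected <- function(x) {
  stopifnot(is(x, "SimulatedStudy"))
  x@h2Expected
}

#' @rdname accessors
#' @export
trueDct <- function(x) {
  stopifnot(is(x, "SimulatedStudy"))
  x@trueDct
}

#' @rdname accessors
#' @export
ctTable <- function(x) {
  stopifnot(is(x, "SimulatedStudy"))
  x@ct
}

#' @rdname accessors
#' @export
twinDesign <- function(x) {
  stopifnot(is(x, "SimulatedStudy"))
  x@design
}

setMethod("show", "TwinDesign", function(object) {
  d <- object@design
  cat(sprintf("TwinDesign with %d samples in %d pairs (%d monozygotic, %d dizygotic)\n",
              nrow(d), length(unique(d$pairId)),
              length(unique(d$pairId[d$zygosity == ZYGOSITY_MZ])),
              length(unique(d$pairId[d$zygosity == ZYGOSITY_DZ]))))
  show(d)
})

setMethod("show", "DetectionPolicy", function(object) {
  cat(sprintf("DetectionPolicy: maxCt = %g cycles; missing markers: %s\n",
              object@maxCt,
              paste(sQuote(object@missingMarkers), collapse = ", ")))
})

setMethod("show", "BinThresholds", function(object) {
  cat(sprintf("BinThresholds: low < %g <= moderate <= %g < high (fold change)\n",
              object@lowBelow, object@highAbove))
})

setMethod("show", "ReferenceBaseline", function(object) {
  cat(sprintf("ReferenceBaseline over controls %s for %d samples\n",
              paste(object@controlNames, collapse = ", "),
              length(object@baseline)))
  print(round(object@baseline, 3))
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat("Falconer twin-study heritability partition\n")
  cat(sprintf("  r (monozygotic) = %.4f   r (dizygotic) = %.4f\n",
              object@rMz, object@rDz))
  cat(sprintf("  H2 raw = %.4f; clamped = %.4f\n",
              object@h2Raw, object@h2Clamped))
  cat(sprintf("  genetics %.0f%% / environment %.0f%%\n",
              100 * object@h2Clamped, 100 * object@environmentShare))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d miRNAs, %d MZ + %d DZ pairs\n",
    "  mu = %g; SDs (baseline, genetic, shared, unique) = %g, %g, %g, %g\n",
    "  refCt = %g cycles; detection limit = %g cycles; seed = %d\n"),
    object@nMirnas, object@nPairsMz, object@nPairsDz, object@mu,
    object@sigmaB, object@sigmaG, object@sigmaC, object@sigmaE,
    object@refCt, object@detectionMaxCt, object@seed))
})

setMethod("show", "SimulatedStudy", function(object) {
  cat(sprintf("SimulatedStudy: %d assays x %d samples; expected H2 = %.3f\n",
              nrow(object@ct), ncol(object@ct), object@h2Expected))
})
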