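#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
NULL

#' CtExperiment: raw qRT-PCR cycle-threshold values
#'
#' A \linkS4class{SummarizedExperiment} holding one assay, \code{"ct"}: raw
#' cycle-threshold (Ct) values with assays (miRNAs plus endogenous controls)
#' in rows and samples in columns. Undetermined wells are stored as \code{NA}.
#' Lower Ct means more abundant template; values are cycles, typically 10-40.
#'
#' @param ct numeric matrix of Ct values (rows = assays, columns = samples);
#'   \code{NA} marks an undetermined well. Row and column names are required
#'   and must be unique.
#' @return A \code{CtExperiment} object.
#' @examples
#' m <- matrix(c(21.5, 30.2, 22.1, 29.8), nrow = 2,
#'             dimnames = list(c("miR-107", "U6-2"), c("S1", "S2")))
#' CtExperiment(m)
#' @export
CtExperiment <- function(ct) {
  ct <- as.matrix(ct)
  storage.mode(ct) <- "double"
  se <- SummarizedExperiment(assays = SimpleList(ct = ct))
  new("CtExperiment", se)
}

#' @rdname CtExperiment
#' @export
setClass("CtExperiment", contains = "SummarizedExperiment")

setValidity("CtExperiment", function(object) {
  msgs <- character(0)
  if (!"ct" %in% names(assays(object)))
    return("assay 'ct' is required")
  m <- assay(object, "ct")
  rn <- rownames(m)
  cn <- colnames(m)
  if (is.null(rn) || anyNA(rn) || any(rn == ""))
    msgs <- c(msgs, "assay (row) names are required")
  else if (anyDuplicated(rn))
    msgs <- c(msgs, sprintf("duplicated assay name(s): %s",
                            paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (is.null(cn) || anyNA(cn) || any(cn == ""))
    msgs <- c(msgs, "sample (column) names are required")
  else if (anyDuplicated(cn))
    msgs <- c(msgs, sprintf("duplicated sample name(s): %s",
                            paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  v <- m[!is.na(m)]
  if (length(v) && (any(!is.finite(v)) || any(v <= 0)))
    msgs <- c(msgs, "all non-missing Ct values must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' ExpressionMatrix: delta-Ct relative expression
#'
#' A \linkS4class{SummarizedExperiment} produced by
#' \code{\link{relativeExpression}}. Assay \code{"dct"} holds delta-Ct values
#' (mean reference Ct minus target Ct, log2 units, larger = more expressed);
#' assay \code{"flagged"} is a logical matrix marking cells that are
#' undetermined or above the detection limit (those cells carry \code{NA} in
#' \code{"dct"}). \code{rowData()$notExpressed} flags miRNAs whose every cell
#' is flagged; rows never include the endogenous controls.
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msgs <- character(0)
  if (!all(c("dct", "flagged") %in% names(assays(object))))
    return("assays 'dct' and 'flagged' are required")
  d <- assay(object, "dct")
  f <- assay(object, "flagged")
  if (!is.logical(f) || !identical(dim(d), dim(f)))
    msgs <- c(msgs, "'flagged' must be a logical matrix matching 'dct'")
  else if (any(f & !is.na(d)))
    msgs <- c(msgs, "flagged cells must carry no numeric dct value")
  if (!"notExpressed" %in% names(rowData(object)))
    msgs <- c(msgs, "rowData column 'notExpressed' is required")
  if (length(msgs)) msgs else TRUE
})

#' TwinDesign: pair membership and zygosity of samples
#'
#' Maps each sample of a Ct table to a twin pair, a member slot (A or B) and a
#' zygosity. Zygosity tokens \code{"identical"}, \code{"MZ"} (any case) are
#' normalized to \code{"monozygotic"}; \code{"fraternal"}, \code{"DZ"} to
#' \code{"dizygotic"}. Each pair must have exactly two samples with distinct
#' members.
#'
#' @param sampleId,pairId,member,zygosity character vectors of equal length,
#'   one entry per sample.
#' @return A \code{TwinDesign} object.
#' @examples
#' TwinDesign(sampleId = c("ID_A", "ID_B", "FR_A", "FR_B"),
#'            pairId   = c("P1", "P1", "P2", "P2"),
#'            member   = c("A", "B", "A", "B"),
#'            zygosity = c("identical", "identical", "fraternal", "fraternal"))
#' @export
TwinDesign <- function(sampleId, pairId, member, zygosity) {
  new("TwinDesign", design = DataFrame(
    sampleId = as.character(sampleId),
    pairId = as.character(pairId),
    member = toupper(trimws(as.character(member))),
    zygosity = normalizeZygosity(zygosity)))
}

#' @rdname TwinDesign
#' @export
setClass("TwinDesign", representation(design = "DataFrame"))

setValidity("TwinDesign", function(object) {
  d <- object@design
  msgs <- character(0)
  need <- c("sampleId", "pairId", "member", "zygosity")
  if (!all(need %in% colnames(d)))
    return(sprintf("design must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(d$sampleId))
    msgs <- c(msgs, sprintf("duplicated sample id(s): %s",
              paste(unique(d$sampleId[duplicated(d$sampleId)]), collapse = ", ")))
  if (!all(d$member %in% c("A", "B")))
    msgs <- c(msgs, "member must be 'A' or 'B'")
  if (!all(d$zygosity %in% c("monozygotic", "dizygotic")))
    msgs <- c(msgs, "zygosity must be 'monozygotic' or 'dizygotic'")
  for (p in unique(d$pairId)) {
    mem <- d$member[d$pairId == p]
    if (length(mem) != 2L || anyDuplicated(mem))
      msgs <- c(msgs, sprintf(
        "pair '%s' must have exactly two samples with members A and B", p))
  }
  if (length(msgs)) msgs else TRUE
})

#' DetectionPolicy: undetermined markers and detection limit
#'
#' Controls how non-detected wells are treated: tokens in
#' \code{missingMarkers} parse as undetermined, and any Ct above \code{maxCt}
#' cycles is considered below the detection limit. The default limit of 40
#' cycles is the usual run length on standard real-time PCR instruments.
#'
#' @param maxCt detection limit in cycles, within (0, 60].
#' @param missingMarkers character tokens treated as undetermined when
#'   reading delimited Ct tables.
#' @return A \code{DetectionPolicy} object.
#' @export
DetectionPolicy <- function(maxCt = 40,
                            missingMarkers = c("Undetermined", "NA", "")) {
  new("DetectionPolicy", maxCt = as.numeric(maxCt),
      missingMarkers = as.character(missingMarkers))
}

#' @rdname DetectionPolicy
#' @export
setClass("DetectionPolicy",
         representation(maxCt = "numeric", missingMarkers = "character"))

setValidity("DetectionPolicy", function(object) {
  if (length(object@maxCt) != 1L || is.na(object@maxCt) ||
      object@maxCt <= 0 || object@maxCt > 60)
    "maxCt must be a single value in (0, 60]" else TRUE
})

#' BinThresholds: discordance fold-change bins
#'
#' Fold-change cut points for binning within-pair expression discordance:
#' folds strictly below \code{lowBelow} are "low", strictly above
#' \code{highAbove} are "high", anything else (including the boundary values
#' themselves) is "moderate".
#'
#' @param lowBelow,highAbove fold-change cut points; must satisfy
#'   \code{1 <= lowBelow < highAbove}.
#' @return A \code{BinThresholds} object.
#' @export
BinThresholds <- function(lowBelow = 2, highAbove = 10) {
  new("BinThresholds", lowBelow = as.numeric(lowBelow),
      highAbove = as.numeric(highAbove))
}

#' @rdname BinThresholds
#' @export
setClass("BinThresholds",
         representation(lowBelow = "numeric", highAbove = "numeric"))

setValidity("BinThresholds", function(object) {
  if (length(object@lowBelow) != 1L || length(object@highAbove) != 1L ||
      object@lowBelow < 1 || object@lowBelow >= object@highAbove)
    "need 1 <= lowBelow < highAbove" else TRUE
})

#' ReferenceBaseline: per-sample endogenous-control summary
#'
#' Per-sample arithmetic mean of the non-missing endogenous-control Ct values
#' (Ct is log2-domain, so this equals a geometric mean of linear abundances),
#' together with the names of the controls that contributed in each sample.
#' Built by \code{\link{referenceBaseline}}.
#'
#' @export
setClass("ReferenceBaseline",
         representation(baseline = "numeric", controlsUsed = "list",
                        controlNames = "character"))

setValidity("ReferenceBaseline", function(object) {
  if (is.null(names(object@baseline)) ||
      !identical(names(object@baseline), names(object@controlsUsed)))
    return("baseline and controlsUsed must share sample names")
  if (any(lengths(object@controlsUsed) < 1L))
    return("every sample needs at least one usable control")
  TRUE
})

#' HeritabilityEstimate: Falconer twin-study variance partition
#'
#' Result of \code{\link{falconerH2}}: the monozygotic and dizygotic co-twin
#' correlations, the raw Falconer estimate \eqn{H^2 = 2(r_{MZ} - r_{DZ})}, its
#' value clamped to [0, 1], and the complementary environment share
#' \eqn{1 - H^2} (using the clamped value so the two shares sum to 1).
#'
#' @export
setClass("HeritabilityEstimate",
         representation(rMz = "numeric", rDz = "numeric",
                        nMz = "numeric", nDz = "numeric",
                        pMz = "numeric", pDz = "numeric",
                        h2Raw = "numeric", h2Clamped = "numeric",
                        environmentShare = "numeric", formula = "character"))

#' SimulationConfig: twin Ct-panel simulator settings
#'
#' Variance-component model for simulated twin qRT-PCR panels. Each miRNA gets
#' a baseline deviation (SD \code{sigmaB}); within each pair, co-twins share a
#' genetic score with correlation 1 (monozygotic) or 0.5 (dizygotic) and
#' marginal SD \code{sigmaG}, a common shared-environment draw (SD
#' \code{sigmaC}) and independent unique-environment draws (SD \code{sigmaE}).
#' True delta-Ct = \code{mu} + baseline + genetic + shared + unique; emitted
#' target Ct = \code{refCt} - delta-Ct, controls sit at \code{refCt} exactly,
#' and any Ct above \code{detectionMaxCt} is emitted as undetermined.
#'
#' Defaults emulate a cord-blood twin panel: 44 miRNAs, two pairs per
#' zygosity, grand mean 10 log2 units and component SDs chosen so that the
#' delta-Ct range spans roughly 5-16 log2 units.
#'
#' @param nMirnas number of target miRNAs (>= 4).
#' @param nPairsMz,nPairsDz number of monozygotic / dizygotic pairs.
#' @param mu grand-mean delta-Ct (log2 units).
#' @param sigmaB SD of the per-miRNA baseline (log2 units).
#' @param sigmaG,sigmaC,sigmaE SDs of the genetic, shared-environment and
#'   unique-environment components (log2 units).
#' @param refCt endogenous-control Ct level (cycles).
#' @param detectionMaxCt detection limit (cycles).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A \code{SimulationConfig} object.
#' @export
SimulationConfig <- function(nMirnas = 44, nPairsMz = 2, nPairsDz = 2,
                             mu = 10, sigmaB = 2, sigmaG = 1.5,
                             sigmaC = 0.5, sigmaE = 1,
                             refCt = 32, detectionMaxCt = 40, seed = 1L) {
  new("SimulationConfig",
      nMirnas = as.integer(nMirnas),
      nPairsMz = as.integer(nPairsMz), nPairsDz = as.integer(nPairsDz),
      mu = as.numeric(mu), sigmaB = as.numeric(sigmaB),
      sigmaG = as.numeric(sigmaG), sigmaC = as.numeric(sigmaC),
      sigmaE = as.numeric(sigmaE),
      kinshipMz = 1.0, kinshipDz = 0.5,
      refCt = as.numeric(refCt), detectionMaxCt = as.numeric(detectionMaxCt),
      seed = as.integer(seed))
}

#' @rdname SimulationConfig
#' @export
setClass("SimulationConfig",
         representation(nMirnas = "integer", nPairsMz = "integer",
                        nPairsDz = "integer", mu = "numeric",
                        sigmaB = "numeric", sigmaG = "numeric",
                        sigmaC = "numeric", sigmaE = "numeric",
                        kinshipMz = "numeric", kinshipDz = "numeric",
                        refCt = "numeric", detectionMaxCt = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@nMirnas < 4L)
    msgs <- c(msgs, "nMirnas must be >= 4")
  if (object@nPairsMz < 0L || object@nPairsDz < 0L ||
      object@nPairsMz + object@nPairsDz < 1L)
    msgs <- c(msgs, "need at least one twin pair")
  sds <- c(object@sigmaB, object@sigmaG, object@sigmaC, object@sigmaE)
  if (any(is.na(sds)) || any(sds < 0))
    msgs <- c(msgs, "all component SDs must be >= 0")
  if (!identical(object@kinshipMz, 1.0) || !identical(object@kinshipDz, 0.5))
    msgs <- c(msgs, "kinship correlations are fixed at 1.0 (MZ) and 0.5 (DZ)")
  if (length(msgs)) msgs else TRUE
})

#' SimulatedStudy: simulator output with ground truth
#'
#' Bundles a simulated \linkS4class{CtExperiment}, its
#' \linkS4class{TwinDesign}, the true per-cell delta-Ct matrix and the
#' closed-form expected heritability
#' \eqn{\sigma_g^2 / (\sigma_b^2+\sigma_g^2+\sigma_c^2+\sigma_e^2)}.
#'
#' @export
setClass("SimulatedStudy",
         representation(ct = "CtExperiment", design = "TwinDesign",
                        trueDct = "matrix", h2Expected = "numeric",
                        config = "SimulationConfig"))
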