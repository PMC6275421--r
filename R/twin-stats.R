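#' Pearson correlation of two expression vectors
#'
#' Sample Pearson correlation after pairwise deletion of entries where either
#' side is missing (e.g. a not-expressed miRNA). Requires at least 3 complete
#' pairs and non-degenerate variance on both sides.
#'
#' @param x,y numeric vectors of equal length (delta-Ct values in the twin
#'   setting, one entry per miRNA).
#' @return The correlation coefficient in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("need at least 3 complete (x, y) pairs", call. = FALSE)
  if (stats::var(x) == 0)
    stop("undefined correlation: 'x' is constant", call. = FALSE)
  if (stats::var(y) == 0)
    stop("undefined correlation: 'y' is constant", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Refers \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} to a t distribution with
#' \eqn{n-2} degrees of freedom. A perfect correlation (|r| = 1) returns an
#' exact-fit p of 0 with a message.
#'
#' @param r correlation coefficient in [-1, 1].
#' @param n number of observation pairs (>= 3).
#' @return Two-sided p-value.
#' @examples
#' correlationPvalue(0, 10)       # 1
#' correlationPvalue(0.6325, 10)  # ~0.0497
#' @export
correlationPvalue <- function(r, n) {
  stopifnot(length(r) == 1L, length(n) == 1L)
  if (is.na(r) || abs(r) > 1)
    stop("r must lie in [-1, 1]", call. = FALSE)
  if (n < 3L)
    stop("need n >= 3 for a defined p-value", call. = FALSE)
  if (abs(r) == 1) {
    message("|r| = 1: exact fit, p = 0")
    return(0)
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Co-twin correlation for one zygosity
#'
#' For each twin pair of the requested zygosity, correlates member A's
#' delta-Ct vector with member B's across miRNAs (dropping, pairwise, miRNAs
#' flagged in either twin). Multiple pairs are pooled on the Fisher z scale,
#' weighting each pair's \eqn{\tanh^{-1}(r)} by \eqn{n - 3}; the combined n is
#' the total number of miRNA observations and the p-value refers the pooled r
#' to the t distribution at that n.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param design a \linkS4class{TwinDesign}.
#' @param zygosity \code{"monozygotic"} or \code{"dizygotic"} (the synonyms
#'   accepted by \code{\link{TwinDesign}} work too).
#' @return A list with \code{zygosity}, \code{r} (pooled), \code{n} (total
#'   miRNA observations), \code{p}, and \code{perPair} (data.frame of
#'   per-pair r and n).
#' @export
zygosityCorrelation <- function(expr, design, zygosity) {
  stopifnot(is(expr, "ExpressionMatrix"), is(design, "TwinDesign"))
  validateDesign(expr, design)
  zygosity <- normalizeZygosity(zygosity)
  d <- as.data.frame(designTable(design))
  d <- d[d$zygosity == zygosity, , drop = FALSE]
  if (!nrow(d))
    stop(sprintf("no %s pairs in the design", zygosity), call. = FALSE)
  dct <- dctMatrix(expr)
  pairs <- unique(d$pairId)
  per <- lapply(pairs, function(p) {
    rows <- d[d$pairId == p, ]
    a <- dct[, rows$sampleId[rows$member == "A"]]
    b <- dct[, rows$sampleId[rows$member == "B"]]
    nOk <- sum(!is.na(a) & !is.na(b))
    if (nOk < 3L)
      stop(sprintf(
        "pair '%s' has %d usable miRNA(s); need >= 3 for a correlation",
        p, nOk), call. = FALSE)
    data.frame(pairId = p, r = pearsonR(a, b), n = nOk,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  if (nrow(per) == 1L) {
    r <- per$r
  } else {
    w <- per$n - 3
    r <- tanh(sum(w * atanh(per$r)) / sum(w))
  }
  n <- sum(per$n)
  list(zygosity = zygosity, r = r, n = n,
       p = correlationPvalue(r, n), perPair = per)
}

#' Falconer heritability partition
#'
#' The classical twin-design estimate of broad-sense heritability,
#' \eqn{H^2 = 2(r_{MZ} - r_{DZ})}: monozygotic co-twins share all their
#' genetic variance, dizygotic co-twins on average half, so twice the
#' correlation gap estimates the genetic share of the phenotypic variance.
#' The raw estimate is clamped to [0, 1] and the environment share is
#' \eqn{1 - H^2} using the clamped value, so the two shares always sum to 1.
#'
#' @param rMz,rDz co-twin correlations for monozygotic and dizygotic pairs,
#'   each in [-1, 1].
#' @param nMz,nDz optional observation counts behind each correlation.
#' @param pMz,pDz optional p-values carried through to reports.
#' @return A \linkS4class{HeritabilityEstimate}.
#' @examples
#' falconerH2(0.61, 0.15)  # genetics 92% / environment 8%
#' @export
falconerH2 <- function(rMz, rDz, nMz = NA_real_, nDz = NA_real_,
                       pMz = NA_real_, pDz = NA_real_) {
  stopifnot(length(rMz) == 1L, length(rDz) == 1L)
  if (is.na(rMz) || is.na(rDz) || abs(rMz) > 1 || abs(rDz) > 1)
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  h2Raw <- 2 * (rMz - rDz)
  h2 <- min(1, max(0, h2Raw))
  new("HeritabilityEstimate",
      rMz = rMz, rDz = rDz,
      nMz = as.numeric(nMz), nDz = as.numeric(nDz),
      pMz = as.numeric(pMz), pDz = as.numeric(pDz),
      h2Raw = h2Raw, h2Clamped = h2, environmentShare = 1 - h2,
      formula = "H2 = 2 * (rMZ - rDZ)")
}
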