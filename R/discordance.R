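#' Within-pair discordance fold change
#'
#' The expression discordance between co-twins for one miRNA is
#' \eqn{2^{|\Delta Ct_A - \Delta Ct_B|}}: the fold difference in relative
#' expression implied by the delta-Ct gap, under the comparative-Ct model of
#' perfect doubling per cycle. It is symmetric in the two twins and always
#' at least 1.
#'
#' @param dctA,dctB delta-Ct values of the two co-twins (log2 units); either
#'   may be a vector.
#' @return Numeric fold change(s), \code{NA} where either input is \code{NA}.
#' @examples
#' discordanceFold(9.07, 16.08)   # 128.89-fold discordance
#' discordanceFold(10.82, 10.05)  # 1.70-fold
#' @export
discordanceFold <- function(dctA, dctB) {
  2^abs(dctA - dctB)
}

#' Bin a discordance fold change
#'
#' Classifies fold changes as \code{"low"} (strictly below the lower cut,
#' default 2), \code{"high"} (strictly above the upper cut, default 10) or
#' \code{"moderate"} otherwise; the boundary values themselves are moderate.
#'
#' @param fold numeric fold change(s), each >= 1; \code{NA} propagates.
#' @param thresholds a \linkS4class{BinThresholds}.
#' @return Character vector over \code{"low"}, \code{"moderate"},
#'   \code{"high"}.
#' @export
classifyDiscordance <- function(fold, thresholds = BinThresholds()) {
  stopifnot(is(thresholds, "BinThresholds"))
  if (any(fold < 1, na.rm = TRUE))
    stop("fold changes must be >= 1", call. = FALSE)
  ifelse(is.na(fold), NA_character_,
         ifelse(fold < thresholds@lowBelow, "low",
                ifelse(fold > thresholds@highAbove, "high", "moderate")))
}

#' Per-pair discordance records
#'
#' Computes, for every (miRNA, twin pair), the co-twin delta-Ct values, the
#' discordance fold and its bin. A miRNA not expressed study-wide, or with a
#' non-detected value in either co-twin of a pair, yields a record with bin
#' \code{"not_expressed"} and no fold; such records are excluded from the bin
#' counts (see \code{\link{binCounts}}).
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param design a \linkS4class{TwinDesign} whose samples are all columns of
#'   \code{expr}.
#' @param thresholds a \linkS4class{BinThresholds}.
#' @return A data.frame with columns \code{mirna}, \code{pairId},
#'   \code{zygosity}, \code{dctA}, \code{dctB}, \code{fold}, \code{bin}.
#' @export
pairDiscordance <- function(expr, design, thresholds = BinThresholds()) {
  stopifnot(is(expr, "ExpressionMatrix"), is(design, "TwinDesign"))
  validateDesign(expr, design)
  d <- as.data.frame(designTable(design))
  dct <- dctMatrix(expr)
  mirnas <- if (is.null(rownames(dct))) character(nrow(dct)) else rownames(dct)
  ne <- apply(flaggedMatrix(expr), 1L, all)
  pairs <- unique(d$pairId)
  recs <- lapply(pairs, function(p) {
    rows <- d[d$pairId == p, ]
    sa <- rows$sampleId[rows$member == "A"]
    sb <- rows$sampleId[rows$member == "B"]
    a <- dct[, sa]
    b <- dct[, sb]
    fold <- discordanceFold(a, b)
    bin <- classifyDiscordance(fold, thresholds)
    undef <- ne | is.na(a) | is.na(b)
    fold[undef] <- NA_real_
    bin[undef] <- "not_expressed"
    data.frame(mirna = mirnas, pairId = rep(p, length(mirnas)),
               zygosity = rep(rows$zygosity[1L], length(mirnas)),
               dctA = unname(a), dctB = unname(b),
               fold = unname(fold), bin = unname(bin),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, recs)
}

#' Bin counts per zygosity
#'
#' Tabulates low/moderate/high discordance per zygosity over the records with
#' a defined fold (not-expressed records are excluded, so a target never
#' detected in the study does not inflate the low-discordance count).
#'
#' @param records the data.frame from \code{\link{pairDiscordance}}, or any
#'   data.frame with columns \code{zygosity} and \code{bin}.
#' @return A data.frame with columns \code{zygosity}, \code{bin},
#'   \code{count}.
#' @export
binCounts <- function(records) {
  keep <- records[records$bin %in% c("low", "moderate", "high"), , drop = FALSE]
  lev <- c("low", "moderate", "high")
  zyg <- c(ZYGOSITY_DZ, ZYGOSITY_MZ)
  tab <- table(factor(keep$zygosity, levels = zyg),
               factor(keep$bin, levels = lev))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  colnames(out) <- c("zygosity", "bin", "count")
  out
}

#' Genetics-versus-environment group of one miRNA
#'
#' Assigns the cross-zygosity discordance pattern of a miRNA to one of four
#' groups: \strong{A} (high discordance in fraternal twins, low in identical
#' twins: expression driven mainly by genetics), \strong{B} (high in both,
#' identical fold at least the fraternal fold: driven mainly by the shared
#' environment), \strong{C} (high in both with the fraternal fold larger:
#' genetics and environment combined), and \strong{D} (high in identical
#' twins only: environment-sensitive despite genetic identity). Any other
#' pattern is \code{"none"}. A tie between two high folds goes to B, C being
#' the fraternal-higher refinement of B.
#'
#' Bins are derived from the folds via \code{thresholds} but can be supplied
#' explicitly (e.g. when a fold is only known to lie in the moderate band).
#'
#' @param fratFold,identFold discordance folds in the dizygotic (fraternal)
#'   and monozygotic (identical) twins; vectors recycle.
#' @param fratBin,identBin optional explicit bins; default derives them from
#'   the folds.
#' @param thresholds a \linkS4class{BinThresholds}.
#' @return Character vector over \code{"A"}, \code{"B"}, \code{"C"},
#'   \code{"D"}, \code{"none"}.
#' @examples
#' assignGroup(8248.98, 1.00)  # "A": genetics
#' assignGroup(61.81, 837.53)  # "B": environment
#' assignGroup(123.63, 22.16)  # "C": both
#' assignGroup(1.00, 10.92)    # "D": environment-sensitive
#' @export
assignGroup <- function(fratFold, identFold, fratBin = NULL, identBin = NULL,
                        thresholds = BinThresholds()) {
  n <- max(length(fratFold), length(identFold))
  fratFold <- rep_len(fratFold, n)
  identFold <- rep_len(identFold, n)
  if (is.null(fratBin)) fratBin <- classifyDiscordance(fratFold, thresholds)
  if (is.null(identBin)) identBin <- classifyDiscordance(identFold, thresholds)
  fratBin <- rep_len(fratBin, n)
  identBin <- rep_len(identBin, n)
  out <- rep("none", n)
  known <- !is.na(fratBin) & !is.na(identBin) &
    fratBin != "not_expressed" & identBin != "not_expressed"
  bothHigh <- known & fratBin == "high" & identBin == "high"
  out[known & fratBin == "high" & identBin == "low"] <- "A"
  out[bothHigh & identFold >= fratFold] <- "B"
  out[bothHigh & fratFold > identFold] <- "C"
  out[known & identBin == "high" & fratBin != "high"] <- "D"
  out
}

#' Group assignment table across zygosities
#'
#' Reduces the per-pair discordance records to one fold per (miRNA, zygosity)
#' — the geometric mean over pairs with a defined fold, i.e. the fold implied
#' by the mean absolute delta-delta-Ct — and applies \code{\link{assignGroup}}
#' to the fraternal/identical fold pair of every miRNA. miRNAs without a
#' defined fold in either zygosity get group \code{"none"} and a
#' \code{notExpressed} flag.
#'
#' @inheritParams binCounts
#' @param thresholds a \linkS4class{BinThresholds}.
#' @return A data.frame with columns \code{mirna}, \code{fraternalFold},
#'   \code{identicalFold}, \code{group}, \code{notExpressed}.
#' @export
groupAssignments <- function(records, thresholds = BinThresholds()) {
  mirnas <- unique(records$mirna)
  foldOf <- function(m, zyg) {
    geomMeanFold(records$fold[records$mirna == m & records$zygosity == zyg])
  }
  frat <- vapply(mirnas, foldOf, numeric(1), zyg = ZYGOSITY_DZ)
  ident <- vapply(mirnas, foldOf, numeric(1), zyg = ZYGOSITY_MZ)
  ne <- is.na(frat) | is.na(ident)
  grp <- rep("none", length(mirnas))
  grp[!ne] <- assignGroup(frat[!ne], ident[!ne], thresholds = thresholds)
  data.frame(mirna = mirnas, fraternalFold = unname(frat),
             identicalFold = unname(ident), group = grp,
             notExpressed = unname(ne),
             row.names = NULL, stringsAsFactors = FALSE)
}
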