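#' Run the full twin discordance / heritability analysis in memory
#'
#' Chains the pipeline stages: endogenous-control baseline, delta-Ct relative
#' expression, per-pair discordance folds and bins, cross-zygosity A-D group
#' assignment, per-zygosity co-twin correlation and the Falconer heritability
#' partition. Correlations are computed on the delta-Ct (log2) scale with
#' pairwise deletion of flagged miRNAs.
#'
#' @param ct a \linkS4class{CtExperiment}.
#' @param design a \linkS4class{TwinDesign} covering the samples of \code{ct}.
#' @param controls endogenous-control assay names.
#' @param thresholds a \linkS4class{BinThresholds}.
#' @param policy a \linkS4class{DetectionPolicy}.
#' @return A list with elements \code{expression}
#'   (\linkS4class{ExpressionMatrix}), \code{records} (per-pair discordance
#'   data.frame), \code{binCounts}, \code{groups}, \code{correlations} (list
#'   with \code{monozygotic} and \code{dizygotic} entries) and
#'   \code{heritability} (\linkS4class{HeritabilityEstimate}).
#' @export
runTwinAnalysis <- function(ct, design, controls = c("U6-2", "SNORD48"),
                            thresholds = BinThresholds(),
                            policy = DetectionPolicy()) {
  stopifnot(is(ct, "CtExperiment"), is(design, "TwinDesign"))
  validateDesign(ct, design)
  baseline <- referenceBaseline(ct, controls)
  expr <- relativeExpression(ct, baseline, policy)
  records <- pairDiscordance(expr, design, thresholds)
  counts <- binCounts(records)
  groups <- groupAssignments(records, thresholds)
  corMz <- zygosityCorrelation(expr, design, ZYGOSITY_MZ)
  corDz <- zygosityCorrelation(expr, design, ZYGOSITY_DZ)
  herit <- falconerH2(corMz$r, corDz$r, nMz = corMz$n, nDz = corDz$n,
                      pMz = corMz$p, pDz = corDz$p)
  list(expression = expr, records = records, binCounts = counts,
       groups = groups,
       correlations = list(monozygotic = corMz, dizygotic = corDz),
       heritability = herit)
}

heritabilityAsList <- function(h) {
  list(r_mz = h@rMz, r_dz = h@rDz, n_mz = h@nMz, n_dz = h@nDz,
       p_mz = h@pMz, p_dz = h@pDz, h2_raw = h@h2Raw,
       h2_clamped = h@h2Clamped, environment_share = h@environmentShare,
       formula = h@formula)
}

#' Run the pipeline end to end and write a report bundle
#'
#' Reads a Ct table and sample sheet (or simulates a study from a
#' \linkS4class{SimulationConfig}), runs \code{\link{runTwinAnalysis}} and
#' writes the report bundle into \code{outDir}:
#' \itemize{
#'   \item \code{expression_matrix.csv} — delta-Ct matrix, flags as "NE";
#'   \item \code{discordance_monozygotic.csv} /
#'     \code{discordance_dizygotic.csv} — per-pair records sorted by fold,
#'     descending;
#'   \item \code{bin_counts.csv}; \code{groups.csv};
#'   \item \code{heritability.json} — correlations and the Falconer
#'     partition;
#'   \item \code{run_log.txt} — configuration echo and seed.
#' }
#' Outputs contain no timestamps, so identical inputs (or an identical
#' simulation seed) reproduce the bundle byte for byte.
#'
#' @param ctPath,samplesPath paths to the Ct table and sample sheet
#'   (delimited text); supply these \emph{or} \code{simConfig}, never both.
#' @param simConfig a \linkS4class{SimulationConfig} or a path to a
#'   YAML/JSON file for \code{\link{readSimulationConfig}}.
#' @param outDir output directory, created if needed.
#' @param dialect delimiter of the input and output tables.
#' @param controls,thresholds,policy as in \code{\link{runTwinAnalysis}}.
#' @param seed optional integer overriding the simulation config seed.
#' @return The \code{\link{runTwinAnalysis}} result list, invisibly, with an
#'   added \code{outDir} element.
#' @export
runPipeline <- function(ctPath = NULL, samplesPath = NULL, simConfig = NULL,
                        outDir, dialect = c("csv", "tsv"),
                        controls = c("U6-2", "SNORD48"),
                        thresholds = BinThresholds(),
                        policy = DetectionPolicy(), seed = NULL) {
  realInput <- !is.null(ctPath) || !is.null(samplesPath)
  if (realInput == !is.null(simConfig))
    stop("supply either ctPath + samplesPath or simConfig, not both",
         call. = FALSE)
  if (realInput && (is.null(ctPath) || is.null(samplesPath)))
    stop("both ctPath and samplesPath are required for real input",
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  if (realInput) {
    ct <- readCtTable(ctPath, dialect, policy@missingMarkers)
    design <- readSampleSheet(samplesPath, dialect)
    sourceDesc <- list(mode = "files", ct = ctPath, samples = samplesPath)
  } else {
    if (is.character(simConfig)) simConfig <- readSimulationConfig(simConfig)
    stopifnot(is(simConfig, "SimulationConfig"))
    if (!is.null(seed)) simConfig@seed <- as.integer(seed)
    study <- simulateTwinCt(simConfig)
    ct <- ctTable(study)
    design <- twinDesign(study)
    writeCtTable(ct, file.path(outDir, "simulated_ct.csv"), dialect)
    writeSampleSheet(design, file.path(outDir, "simulated_samples.csv"),
                     dialect)
    sourceDesc <- list(mode = "simulation", seed = simConfig@seed,
                       h2_expected = h2Expected(study))
  }

  res <- runTwinAnalysis(ct, design, controls, thresholds, policy)

  writeExpressionMatrix(res$expression,
                        file.path(outDir, "expression_matrix.csv"), dialect)
  for (zyg in c(ZYGOSITY_MZ, ZYGOSITY_DZ)) {
    recs <- res$records[res$records$zygosity == zyg, , drop = FALSE]
    recs <- recs[order(-ifelse(is.na(recs$fold), -Inf, recs$fold),
                       recs$mirna), , drop = FALSE]
    recs$fold <- round(recs$fold, 2)
    utils::write.table(recs, file.path(outDir, sprintf("discordance_%s.csv",
                                                       zyg)),
                       sep = sepForDialect(dialect), quote = FALSE,
                       row.names = FALSE)
  }
  utils::write.table(res$binCounts, file.path(outDir, "bin_counts.csv"),
                     sep = sepForDialect(dialect), quote = FALSE,
                     row.names = FALSE)
  groupsOut <- res$groups
  groupsOut$fraternalFold <- round(groupsOut$fraternalFold, 2)
  groupsOut$identicalFold <- round(groupsOut$identicalFold, 2)
  utils::write.table(groupsOut, file.path(outDir, "groups.csv"),
                     sep = sepForDialect(dialect), quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(heritabilityAsList(res$heritability),
                       file.path(outDir, "heritability.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log <- c("twinMiR pipeline run",
           sprintf("input: %s", jsonlite::toJSON(sourceDesc,
                                                 auto_unbox = TRUE,
                                                 digits = NA)),
           sprintf("controls: %s", paste(controls, collapse = ", ")),
           sprintf("bin thresholds: low < %g, high > %g",
                   thresholds@lowBelow, thresholds@highAbove),
           sprintf("detection limit: %g cycles", policy@maxCt))
  writeLines(log, file.path(outDir, "run_log.txt"))
  res$outDir <- outDir
  invisible(res)
}

#' Summarize a report bundle
#'
#' Reads the files written by \code{\link{runPipeline}} and prints a compact
#' summary: discordance bin counts per zygosity, A-D group memberships, the
#' co-twin correlations, and the heritability partition as whole-number
#' percentages. Every printed number is read from the bundle; nothing is
#' recomputed.
#'
#' @param dir the bundle directory.
#' @param dialect delimiter used when the bundle was written.
#' @return The printed lines, invisibly.
#' @export
summarizeRun <- function(dir, dialect = c("csv", "tsv")) {
  sep <- sepForDialect(dialect)
  need <- c("bin_counts.csv", "groups.csv", "heritability.json")
  absent <- need[!file.exists(file.path(dir, need))]
  if (length(absent))
    stop(sprintf("malformed bundle: missing %s", paste(absent, collapse = ", ")),
         call. = FALSE)
  counts <- utils::read.table(file.path(dir, "bin_counts.csv"), sep = sep,
                              header = TRUE, stringsAsFactors = FALSE)
  groups <- utils::read.table(file.path(dir, "groups.csv"), sep = sep,
                              header = TRUE, stringsAsFactors = FALSE)
  herit <- jsonlite::read_json(file.path(dir, "heritability.json"),
                               simplifyVector = TRUE)
  lines <- character(0)
  for (zyg in unique(counts$zygosity)) {
    cz <- counts[counts$zygosity == zyg, ]
    lines <- c(lines, sprintf("discordance bins (%s): %s", zyg,
                              paste(sprintf("%s=%d", cz$bin, cz$count),
                                    collapse = ", ")))
  }
  classified <- groups[groups$group %in% c("A", "B", "C", "D"), , drop = FALSE]
  if (!nrow(classified)) {
    lines <- c(lines, "no miRNAs classified")
  } else {
    for (g in sort(unique(classified$group)))
      lines <- c(lines, sprintf("group %s: %s", g,
                                paste(classified$mirna[classified$group == g],
                                      collapse = ", ")))
  }
  lines <- c(lines,
             sprintf("r (monozygotic) = %.2f (n = %g, p = %.4g)",
                     herit$r_mz, as.numeric(herit$n_mz), herit$p_mz),
             sprintf("r (dizygotic) = %.2f (n = %g, p = %.4g)",
                     herit$r_dz, as.numeric(herit$n_dz), herit$p_dz),
             sprintf("H2 = %.0f%%: genetics %.0f%% / environment %.0f%%",
                     100 * herit$h2_clamped, 100 * herit$h2_clamped,
                     100 * herit$environment_share))
  writeLines(lines)
  invisible(lines)
}
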