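#' Simulate a twin Ct panel with known variance components
#'
#' Draws a twin qRT-PCR study from the variance-component model of
#' \code{\link{SimulationConfig}}. For miRNA \eqn{m}, baseline
#' \eqn{b_m \sim N(0, \sigma_b^2)} is shared by everyone; within a pair, twin
#' A's genetic score is \eqn{\sigma_g Z} and twin B's is
#' \eqn{\sigma_g(\rho Z + \sqrt{1-\rho^2} Z')} with independent standard
#' normals \eqn{Z, Z'} and \eqn{\rho} = 1 (monozygotic) or 0.5 (dizygotic),
#' giving marginal SD \eqn{\sigma_g} and within-pair correlation \eqn{\rho}.
#' A shared-environment draw (SD \eqn{\sigma_c}) is common to both twins and
#' a unique-environment draw (SD \eqn{\sigma_e}) is independent per twin.
#' True delta-Ct = mu + baseline + genetic + shared + unique; the emitted
#' target Ct is refCt - delta-Ct, the two control assays (U6-2, SNORD48) sit
#' at refCt exactly, and Cts above the detection limit become undetermined.
#'
#' Co-twin correlations here are computed \emph{across the miRNA panel} of a
#' single pair (one expression vector per twin), so the per-miRNA baseline
#' variance \eqn{\sigma_b^2} contributes to both zygosities' correlations and
#' cancels from the Falconer difference — see
#' \code{\link{expectedCorrelation}}.
#'
#' All randomness flows from the config seed through a locally scoped
#' generator; the caller's RNG state is untouched and identical seeds give
#' bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SimulatedStudy}.
#' @examples
#' study <- simulateTwinCt(SimulationConfig(seed = 7))
#' ctTable(study)
#' h2Expected(study)
#' @export
simulateTwinCt <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nm <- config@nMirnas
  mirnas <- sprintf("miR-sim-%03d", seq_len(nm))
  zyg <- c(rep(ZYGOSITY_MZ, config@nPairsMz), rep(ZYGOSITY_DZ, config@nPairsDz))
  pairIds <- c(sprintf("MZ%d", seq_len(config@nPairsMz)),
               sprintf("DZ%d", seq_len(config@nPairsDz)))
  samples <- as.vector(rbind(paste0(pairIds, "_A"), paste0(pairIds, "_B")))

  dct <- withLocalSeed(config@seed, {
    base <- stats::rnorm(nm, 0, config@sigmaB)
    cols <- lapply(seq_along(pairIds), function(i) {
      rho <- if (zyg[i] == ZYGOSITY_MZ) config@kinshipMz else config@kinshipDz
      g1 <- stats::rnorm(nm)
      g2 <- stats::rnorm(nm)
      gA <- config@sigmaG * g1
      gB <- config@sigmaG * (rho * g1 + sqrt(1 - rho^2) * g2)
      shared <- stats::rnorm(nm, 0, config@sigmaC)
      eA <- stats::rnorm(nm, 0, config@sigmaE)
      eB <- stats::rnorm(nm, 0, config@sigmaE)
      cbind(config@mu + base + gA + shared + eA,
            config@mu + base + gB + shared + eB)
    })
    m <- do.call(cbind, cols)
    dimnames(m) <- list(mirnas, samples)
    m
  })

  ct <- config@refCt - dct
  ct[ct > config@detectionMaxCt] <- NA_real_
  ctrl <- matrix(config@refCt, nrow = 2L, ncol = ncol(ct),
                 dimnames = list(c("U6-2", "SNORD48"), samples))
  design <- TwinDesign(sampleId = samples,
                       pairId = rep(pairIds, each = 2L),
                       member = rep(c("A", "B"), length(pairIds)),
                       zygosity = rep(zyg, each = 2L))
  tot <- config@sigmaB^2 + config@sigmaG^2 + config@sigmaC^2 + config@sigmaE^2
  new("SimulatedStudy",
      ct = CtExperiment(rbind(ct, ctrl)),
      design = design, trueDct = dct,
      h2Expected = if (tot > 0) config@sigmaG^2 / tot else NA_real_,
      config = config)
}

#' Closed-form expected co-twin correlation
#'
#' Under the simulator's model the across-panel correlation between co-twins
#' is \deqn{r = (\sigma_b^2 + \rho \sigma_g^2 + \sigma_c^2) /
#' (\sigma_b^2 + \sigma_g^2 + \sigma_c^2 + \sigma_e^2)} with \eqn{\rho} the
#' zygosity's kinship correlation. Consequently
#' \eqn{2(r_{MZ} - r_{DZ}) = \sigma_g^2 / \sigma_{tot}^2}: the Falconer
#' estimate recovers the simulated heritability, independent of the baseline
#' and shared-environment variances.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param zygosity \code{"monozygotic"} or \code{"dizygotic"}.
#' @return The expected Pearson correlation.
#' @export
expectedCorrelation <- function(config, zygosity) {
  stopifnot(is(config, "SimulationConfig"))
  zygosity <- normalizeZygosity(zygosity)
  rho <- if (zygosity == ZYGOSITY_MZ) config@kinshipMz else config@kinshipDz
  tot <- config@sigmaB^2 + config@sigmaG^2 + config@sigmaC^2 + config@sigmaE^2
  if (tot == 0)
    stop("expected correlation undefined: total variance is zero",
         call. = FALSE)
  (config@sigmaB^2 + rho * config@sigmaG^2 + config@sigmaC^2) / tot
}

#' Read a simulation config from YAML or JSON
#'
#' Keys mirror the arguments of \code{\link{SimulationConfig}} (snake_case
#' accepted, e.g. \code{n_mirnas}, \code{sigma_b}); absent keys keep their
#' defaults. Files ending in \code{.json} are parsed as JSON, anything else
#' as YAML.
#'
#' @param path path to the config file.
#' @return A \linkS4class{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(vals)) stop("config must be a mapping", call. = FALSE)
  canon <- c(n_mirnas = "nMirnas", n_pairs_mz = "nPairsMz",
             n_pairs_dz = "nPairsDz", mu = "mu", sigma_b = "sigmaB",
             sigma_g = "sigmaG", sigma_c = "sigmaC", sigma_e = "sigmaE",
             ref_ct = "refCt", detection_max_ct = "detectionMaxCt",
             seed = "seed")
  nm <- names(vals)
  nm <- ifelse(nm %in% names(canon), canon[nm], nm)
  names(vals) <- nm
  known <- names(formals(SimulationConfig))
  unknown <- setdiff(nm, known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  do.call(SimulationConfig, vals)
}
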