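test_that("identical seeds give bit-identical studies; the global RNG is untouched", {
  cfg <- SimulationConfig(nMirnas = 20, seed = 99)
  s1 <- simulateTwinCt(cfg)
  set.seed(1234)
  before <- .Random.seed
  s2 <- simulateTwinCt(cfg)
  expect_identical(before, .Random.seed)
  expect_identical(ctMatrix(ctTable(s1)), ctMatrix(ctTable(s2)))
  expect_identical(trueDct(s1), trueDct(s2))
  s3 <- simulateTwinCt(SimulationConfig(nMirnas = 20, seed = 100))
  expect_false(identical(ctMatrix(ctTable(s1)), ctMatrix(ctTable(s3))))
})

test_that("zero variance components give identical co-twins and all-low bins", {
  cfg <- SimulationConfig(nMirnas = 6, nPairsMz = 1, nPairsDz = 1,
                          sigmaB = 0, sigmaG = 0, sigmaC = 0, sigmaE = 0,
                          seed = 2)
  st <- simulateTwinCt(cfg)
  ct <- ctTable(st)
  expr <- relativeExpression(ct, referenceBaseline(ct))
  recs <- pairDiscordance(expr, twinDesign(st))
  expect_true(all(recs$fold == 1))
  expect_true(all(recs$bin == "low"))
})

test_that("expected heritability and correlations follow the closed forms", {
  cfg <- SimulationConfig(nMirnas = 10, sigmaB = 1, sigmaG = 1, sigmaC = 0,
                          sigmaE = sqrt(2))
  expect_equal(h2Expected(simulateTwinCt(cfg)), 0.25)
  cfg2 <- SimulationConfig(nMirnas = 10, sigmaB = 0, sigmaG = 1, sigmaC = 0,
                           sigmaE = 1)
  expect_equal(expectedCorrelation(cfg2, "monozygotic"), 0.5)
  expect_equal(expectedCorrelation(cfg2, "dizygotic"), 0.25)
  # no genetic variance: zygosities coincide, implied heritability zero
  cfg3 <- SimulationConfig(nMirnas = 10, sigmaB = 1, sigmaG = 0, sigmaC = 1,
                           sigmaE = 1)
  expect_equal(expectedCorrelation(cfg3, "MZ"), expectedCorrelation(cfg3, "DZ"))
  # no unique environment, no baseline: MZ co-twins correlate perfectly
  cfg4 <- SimulationConfig(nMirnas = 10, sigmaB = 0, sigmaG = 1, sigmaC = 0,
                           sigmaE = 0)
  expect_equal(expectedCorrelation(cfg4, "monozygotic"), 1)
  cfg0 <- SimulationConfig(nMirnas = 10, sigmaB = 0, sigmaG = 0, sigmaC = 0,
                           sigmaE = 0)
  expect_error(expectedCorrelation(cfg0, "MZ"), "total variance")
})

test_that("for both zygosities, Falconer recovers 2(rMZ - rDZ) = sigma_g^2 / total", {
  set.seed(6)
  for (i in 1:10) {
    cfg <- SimulationConfig(nMirnas = 10, sigmaB = runif(1, 0, 2),
                            sigmaG = runif(1, 0, 2), sigmaC = runif(1, 0, 1),
                            sigmaE = runif(1, 0.2, 2))
    st <- simulateTwinCt(cfg)
    expect_equal(2 * (expectedCorrelation(cfg, "MZ") -
                        expectedCorrelation(cfg, "DZ")),
                 h2Expected(st), tolerance = 1e-12)
  }
})

test_that("increasing unique-environment SD strictly lowers both expected correlations", {
  es <- c(0.2, 0.5, 1, 1.5, 2.5)
  for (zyg in c("MZ", "DZ")) {
    r <- vapply(es, function(e)
      expectedCorrelation(SimulationConfig(nMirnas = 8, sigmaB = 1, sigmaG = 1,
                                           sigmaC = 0.5, sigmaE = e), zyg),
      numeric(1))
    expect_true(all(diff(r) < 0))
  }
})

test_that("empirical co-twin correlations converge to the closed form", {
  nm <- 4000
  cfg <- SimulationConfig(nMirnas = nm, nPairsMz = 1, nPairsDz = 1,
                          sigmaB = 1, sigmaG = sqrt(2), sigmaC = sqrt(0.5),
                          sigmaE = sqrt(1.5), seed = 17,
                          detectionMaxCt = 60)
  st <- simulateTwinCt(cfg)
  res <- runTwinAnalysis(ctTable(st), twinDesign(st),
                         policy = DetectionPolicy(maxCt = 60))
  for (zyg in c("monozygotic", "dizygotic")) {
    rExp <- expectedCorrelation(cfg, zyg)
    rObs <- res$correlations[[zyg]]$r
    se <- (1 - rExp^2) / sqrt(nm)
    expect_lt(abs(rObs - rExp), 3 * se)
  }
})

test_that("targets drifting past the detection limit are emitted undetermined", {
  cfg <- SimulationConfig(nMirnas = 200, nPairsMz = 1, nPairsDz = 1,
                          mu = -6, sigmaB = 2, sigmaG = 1, sigmaC = 0.5,
                          sigmaE = 1, refCt = 32, detectionMaxCt = 40,
                          seed = 5)
  st <- simulateTwinCt(cfg)
  m <- ctMatrix(ctTable(st))
  targets <- setdiff(rownames(m), c("U6-2", "SNORD48"))
  expect_gt(sum(is.na(m[targets, ])), 0)
  expect_true(all(m[targets, ][!is.na(m[targets, ])] <= 40))
  # controls sit exactly at the reference level
  expect_true(all(m[c("U6-2", "SNORD48"), ] == 32))
  expect_identical(ctMatrix(ctTable(st))[targets, ] ,
                   ifelse(32 - trueDct(st) > 40, NA_real_, 32 - trueDct(st)))
})

test_that("simulation configs load from YAML and JSON with snake_case keys", {
  ty <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_mirnas: 12", "sigma_g: 1.25", "seed: 7"), ty)
  cfg <- readSimulationConfig(ty)
  expect_identical(cfg@nMirnas, 12L)
  expect_equal(cfg@sigmaG, 1.25)
  expect_identical(cfg@seed, 7L)
  tj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nMirnas": 8, "sigmaE": 0.75}', tj)
  cfg2 <- readSimulationConfig(tj)
  expect_identical(cfg2@nMirnas, 8L)
  expect_equal(cfg2@sigmaE, 0.75)
  tb <- withr::local_tempfile(fileext = ".yaml")
  writeLines("bogus_knob: 3", tb)
  expect_error(readSimulationConfig(tb), "bogus_knob")
})

test_that("config validity rejects degenerate panels and altered kinship", {
  expect_error(SimulationConfig(nMirnas = 2), "nMirnas")
  expect_error(SimulationConfig(sigmaE = -1), "SD")
  expect_error(new("SimulationConfig", nMirnas = 10L, nPairsMz = 1L,
                   nPairsDz = 1L, mu = 10, sigmaB = 1, sigmaG = 1, sigmaC = 1,
                   sigmaE = 1, kinshipMz = 1, kinshipDz = 0.4, refCt = 32,
                   detectionMaxCt = 40, seed = 1L),
               "kinship")
})
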