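test_that("discordance folds reproduce published co-twin examples", {
  # fraternal and identical delta-Ct pairs with their tabulated folds
  expect_equal(discordanceFold(9.07, 16.08), 128.89, tolerance = 0.01 / 128.89)
  expect_equal(discordanceFold(10.82, 10.05), 1.70, tolerance = 0.01 / 1.70)
  expect_equal(discordanceFold(5, 5), 1.00)
})

test_that("folds are symmetric, >= 1, and exactly 2^|ddCt|", {
  set.seed(21)
  for (i in 1:50) {
    a <- runif(1, -5, 18)
    b <- runif(1, -5, 18)
    f <- discordanceFold(a, b)
    expect_identical(f, discordanceFold(b, a))
    expect_gte(f, 1)
    expect_equal(log2(f), abs(a - b), tolerance = 1e-12)
  }
})

test_that("bins use strict thresholds with boundaries moderate", {
  t <- BinThresholds()
  expect_identical(classifyDiscordance(c(128.89, 1.97, 2.0, 10.0, 10.63, 1,
                                         9.99, 2.01), t),
                   c("high", "low", "moderate", "moderate", "high", "low",
                     "moderate", "moderate"))
  expect_error(classifyDiscordance(0.5, t), ">= 1")
  expect_error(BinThresholds(10, 2))
})

test_that("every finite fold lands in exactly one bin", {
  set.seed(9)
  folds <- c(2^runif(200, 0, 14), 1, 2, 10)
  bins <- classifyDiscordance(folds)
  expect_false(anyNA(bins))
  expect_true(all(bins %in% c("low", "moderate", "high")))
  # monotone: larger |ddCt| never moves a bin from high toward low
  ord <- order(folds)
  rank <- c(low = 1, moderate = 2, high = 3)
  expect_true(all(diff(rank[bins[ord]]) >= 0))
})

test_that("pairDiscordance yields one record per miRNA and pair", {
  dct <- matrix(c(5, 5, NA, NA,
                  3, 8, NA, NA),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("m1", "m2"),
                                c("DZ1_A", "DZ1_B", "MZ1_A", "MZ1_B")))
  dct2 <- dct
  dct2[, 3:4] <- c(1, 1, 2, 2)
  expr <- exprFromDct(dct2)
  recs <- pairDiscordance(expr, twoPairDesign())
  dz <- recs[recs$zygosity == "dizygotic", ]
  expect_equal(dz$fold, c(1, 32))       # 2^0 and 2^5
  expect_identical(dz$bin, c("low", "high"))
  expect_identical(nrow(recs), 4L)
})

test_that("not-expressed miRNAs carry the not_expressed bin, no fold", {
  dct <- matrix(c(NA, NA, NA, NA,
                  4, 6, 4, NA),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("gone", "partial"),
                                c("MZ1_A", "MZ1_B", "DZ1_A", "DZ1_B")))
  recs <- pairDiscordance(exprFromDct(dct), twoPairDesign())
  expect_true(all(recs$bin[recs$mirna == "gone"] == "not_expressed"))
  pr <- recs[recs$mirna == "partial", ]
  expect_identical(pr$bin[pr$zygosity == "monozygotic"], "moderate")
  expect_identical(pr$bin[pr$zygosity == "dizygotic"], "not_expressed")
  counts <- binCounts(recs)
  expect_identical(sum(counts$count), 1L)  # only the defined record counts
})

test_that("an empty miRNA set gives empty records and zero counts", {
  dct <- matrix(numeric(0), nrow = 0, ncol = 4,
                dimnames = list(NULL, c("MZ1_A", "MZ1_B", "DZ1_A", "DZ1_B")))
  recs <- pairDiscordance(exprFromDct(dct), twoPairDesign())
  expect_identical(nrow(recs), 0L)
  expect_true(all(binCounts(recs)$count == 0L))
})

test_that("group assignment follows the cross-zygosity rule", {
  # published exemplars of each group
  expect_identical(assignGroup(8248.98, 1.00), "A")
  expect_identical(assignGroup(61.81, 837.53), "B")
  expect_identical(assignGroup(123.63, 22.16), "C")
  expect_identical(assignGroup(1.00, 10.92), "D")
  # ties between two high folds go to B; moderate patterns are unclassified
  expect_identical(assignGroup(50, 50), "B")
  expect_identical(assignGroup(5, 5), "none")
  expect_identical(assignGroup(5, 1.2), "none")
  # D needs only "not high" fraternal, which can be a bin-level fact
  expect_identical(assignGroup(NA, 23.75, fratBin = "moderate"), "D")
  expect_identical(assignGroup(NA, 1.5, fratBin = "not_expressed"), "none")
})

test_that("multi-pair folds combine as geometric means before grouping", {
  dct <- matrix(c(0, 2, 0, 4,    # MZ folds 4 and 16 -> geometric mean 8
                  0, 5, 0, 5),   # DZ folds 32 and 32 -> 32
                nrow = 2, byrow = TRUE,
                dimnames = list(c("m1", "m2"),
                                c("MZ1_A", "MZ1_B", "MZ2_A", "MZ2_B")))
  colnames(dct) <- c("MZ1_A", "MZ1_B", "MZ2_A", "MZ2_B")
  design <- TwinDesign(sampleId = colnames(dct),
                       pairId = c("MZ1", "MZ1", "MZ2", "MZ2"),
                       member = rep(c("A", "B"), 2),
                       zygosity = rep("MZ", 4))
  recs <- pairDiscordance(exprFromDct(dct), design)
  ga <- groupAssignments(recs)
  expect_equal(ga$identicalFold[ga$mirna == "m1"], 8)
  expect_equal(ga$identicalFold[ga$mirna == "m2"], 32)
  expect_true(all(ga$group == "none"))  # no fraternal fold available
  expect_true(all(ga$notExpressed))
})
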