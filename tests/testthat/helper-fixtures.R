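# shared fixture builders and independent oracles

toyCtMatrix <- function() {
  matrix(c(21.93, 22.30,
           25.10, NA,
           32.00, 31.80,
           30.50, 30.90),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("miR-107", "miR-20a", "U6-2", "SNORD48"),
                         c("S1", "S2")))
}

extdataPath <- function(file) {
  system.file("extdata", file, package = "twinMiR", mustWork = TRUE)
}

loadPublishedFolds <- function() {
  read.csv(extdataPath("cordblood_twin_folds.csv"), stringsAsFactors = FALSE)
}

loadPublishedGroups <- function() {
  read.csv(extdataPath("cordblood_twin_groups.csv"), stringsAsFactors = FALSE)
}

# direct sum-formula Pearson correlation, independent of stats::cor
pearsonOracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# two-member twin design over the given sample names
twoPairDesign <- function() {
  TwinDesign(sampleId = c("MZ1_A", "MZ1_B", "DZ1_A", "DZ1_B"),
             pairId = c("MZ1", "MZ1", "DZ1", "DZ1"),
             member = c("A", "B", "A", "B"),
             zygosity = c("MZ", "MZ", "DZ", "DZ"))
}

# ExpressionMatrix built directly from a dct matrix (bypasses normalization)
exprFromDct <- function(dct, flagged = is.na(dct)) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dct = dct, flagged = flagged),
    rowData = S4Vectors::DataFrame(notExpressed = apply(flagged, 1, all),
                                   row.names = rownames(dct)))
  new("ExpressionMatrix", se)
}
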