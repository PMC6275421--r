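# internal helpers shared across modules

ZYGOSITY_MZ <- "monozygotic"
ZYGOSITY_DZ <- "dizygotic"

normalizeZygosity <- function(z) {
  z0 <- tolower(trimws(as.character(z)))
  out <- ifelse(z0 %in% c("monozygotic", "identical", "mz"), ZYGOSITY_MZ,
         ifelse(z0 %in% c("dizygotic", "fraternal", "dz"), ZYGOSITY_DZ,
                NA_character_))
  if (anyNA(out)) {
    bad <- unique(as.character(z)[is.na(out)])
    stop(sprintf("unknown zygosity token(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  out
}

sepForDialect <- function(dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") "," else "\t"
}

# run code with a locally seeded RNG, restoring global state afterwards
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# geometric mean of fold changes == 2^mean(log2 folds)
geomMeanFold <- function(folds) {
  folds <- folds[!is.na(folds)]
  if (!length(folds)) return(NA_real_)
  2^mean(log2(folds))
}

formatCtValue <- function(x, missingMarker) {
  ifelse(is.na(x), missingMarker, sprintf("%.17g", x))
}
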