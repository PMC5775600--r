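# Small in-code fixtures shared across test files.

# ExpressionDataset from a matrix of values, auto-named probes/samples.
makeDataset <- function(values, id = "D1", probes = NULL, samples = NULL) {
  values <- as.matrix(values)
  rownames(values) <- probes %||% sprintf("P%d", seq_len(nrow(values)))
  colnames(values) <- samples %||% sprintf("S%d", seq_len(ncol(values)))
  ExpressionDataset(values, id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dataset whose first row ("T") has an exact sample sd: values
# c(m - d, m, m + d) have variance d^2, and sqrt of an exactly
# representable square is exact.
makeTargetSDDataset <- function(sdValue, id, nNull = 2L) {
  target <- c(5 - sdValue, 5, 5 + sdValue)
  null <- matrix(seq_len(3L * nNull), nNull, 3L)
  makeDataset(rbind(target, null), id,
              probes = c("T", sprintf("N%d", seq_len(nNull))))
}

# Write a tiny GMT file and return its path.
writeGMTLines <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# A small compendium with planted signal, cheap enough for unit tests.
smallTruth <- function(seed = 11L, ...) {
  defaults <- list(seed = seed, nDatasets = 6L, samplesPerDataset = 25L,
                   nPlanted = 15L, plantedR = 0.7, nNull = 120L,
                   targetSD = 0.5)
  args <- utils::modifyList(defaults, list(...))
  do.call(syntheticTruth, args)
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
enumUpperTail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # treat genes 1..K as the set
  mean(hits >= k)
}
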