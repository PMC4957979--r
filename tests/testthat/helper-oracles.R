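# Independent oracles, kept deliberately naive: per-position explicit sums,
# no sharing with the package's vectorised implementation.

oracleSmooth <- function(y, b) {
  L <- length(y)
  out <- numeric(L)
  for (i in seq_len(L)) {
    num <- 0
    den <- 0
    for (j in seq_len(L)) {
      k <- exp(-((i - j)^2) / (2 * b^2))
      num <- num + k * y[j]
      den <- den + k
    }
    out[i] <- num / den
  }
  out
}

# faster oracle (explicit per-position sum, vectorised inner loop) for the
# larger acceptance sweep
oracleSmoothFast <- function(y, b) {
  L <- length(y)
  x <- seq_len(L)
  vapply(x, function(i) {
    k <- exp(-((i - x)^2) / (2 * b^2))
    sum(k * y) / sum(k)
  }, numeric(1))
}

# toy record builder
makeRecords <- function(position, rawLabel, caseId = "",
                        proteinChange = NULL,
                        shallowDeletion = FALSE,
                        concurrentTruncating = FALSE) {
  n <- length(position)
  if (is.null(proteinChange))
    proteinChange <- sprintf("p.A%dV", position)
  data.frame(caseId = rep_len(as.character(caseId), n),
             position = as.integer(position),
             rawLabel = rep_len(rawLabel, n),
             proteinChange = rep_len(proteinChange, n),
             shallowDeletion = rep_len(shallowDeletion, n),
             concurrentTruncating = rep_len(concurrentTruncating, n),
             stringsAsFactors = FALSE)
}
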