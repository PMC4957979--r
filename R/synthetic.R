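.AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a SyntheticConfig
#'
#' Parameters of the synthetic catalog generator, defaulting to the study
#' conditions of the ATM analysis: a 3057-aa protein, 286 non-synonymous
#' unique mutations of which 206/286 are missense, an enriched kinase
#' domain at residues 2711-2962 with in-domain rate ratio 2.5, a
#' silent:non-silent ratio of 0.5 and a concurrent-loss probability of
#' 105/206 among missense records.
#'
#' @param L protein length (aa, including the stop codon).
#' @param nNonsilent non-synonymous unique mutations to generate.
#' @param missenseFraction share of non-silent records that are missense.
#' @param domain enriched interval, a [DomainSpec-class].
#' @param enrichmentFactor multiplicative in-domain rate ratio (f = 1 gives
#'   a uniform catalog).
#' @param silentRatio silent:non-silent count ratio; the generator emits
#'   exactly \code{round(silentRatio * nNonsilent)} silent records.
#' @param concurrentLossProb probability a missense record carries a
#'   concurrent shallow-deletion flag.
#' @param duplicationRate fraction of records replaced by copies of earlier
#'   records (distinct cases, same protein change), collapsed later by
#'   deduplication. Default 0: all records deduplicate to distinct uniques.
#' @param enrichTruncating apply the enrichment to truncating instead of
#'   missense positions (negative-control switch).
#' @param seed RNG seed; generation is a pure function of the config.
#' @return A [SyntheticConfig-class].
#' @examples
#' syntheticConfig(nNonsilent = 100, enrichmentFactor = 1, seed = 3)
#' @export
syntheticConfig <- function(L = 3057L, nNonsilent = 286L,
                            missenseFraction = 206 / 286,
                            domain = kinaseDomain(),
                            enrichmentFactor = 2.5,
                            silentRatio = 0.5,
                            concurrentLossProb = 105 / 206,
                            duplicationRate = 0,
                            enrichTruncating = FALSE,
                            seed = 1L) {
  new("SyntheticConfig", L = as.integer(L),
      nNonsilent = as.integer(nNonsilent),
      missenseFraction = missenseFraction, domain = domain,
      enrichmentFactor = enrichmentFactor, silentRatio = silentRatio,
      concurrentLossProb = concurrentLossProb,
      duplicationRate = duplicationRate,
      enrichTruncating = isTRUE(enrichTruncating), seed = as.integer(seed))
}

# distinct protein-change tokens for k-th occurrence at a (class, position)
.synthToken <- function(position, class, occurrence) {
  ref <- .AA1[(position %% 20L) + 1L]
  alt <- character(length(position))
  isMis <- class %in% c("missense", "silent")
  if (any(isMis)) {
    pool <- lapply(ref[isMis], function(r) setdiff(.AA1, r))
    k <- occurrence[isMis]
    alt[isMis] <- mapply(function(p, kk) p[((kk - 1L) %% 19L) + 1L],
                         pool, k)
    alt[isMis] <- ifelse(k > 19L,
                         paste0(alt[isMis], "_", (k - 1L) %/% 19L),
                         alt[isMis])
  }
  if (any(!isMis)) {
    k <- occurrence[!isMis]
    alt[!isMis] <- ifelse(k > 1L, paste0("fs_", k), "fs")
  }
  sprintf("p.%s%d%s", ref, position, alt)
}

.sampleEnriched <- function(n, L, domain, f) {
  if (n == 0L) return(integer(0))
  prob <- rep(1, L)
  prob[domain@start:domain@end] <- f
  sample.int(L, n, replace = TRUE, prob = prob)
}

#' Generate a synthetic mutation catalog
#'
#' Draws a catalog of mutation records with the statistical structure the
#' density and enrichment analyses assume: missense positions from a
#' piecewise-uniform density with rate proportional to the enrichment
#' factor inside the domain and 1 outside, truncating and silent positions
#' uniform on \code{1:L}, labels drawn from the TCGA vocabulary consistent
#' with each class, and synthetic protein-change tokens built so that
#' deduplication keeps every record distinct (unless \code{duplicationRate}
#' is set). Each record gets its own synthetic case; missense records carry
#' a concurrent shallow-deletion flag with probability
#' \code{concurrentLossProb}.
#'
#' @param config a [SyntheticConfig-class].
#' @return data.frame of mutation records as produced by [readMaf()]
#'   (columns caseId, position, rawLabel, proteinChange, shallowDeletion,
#'   concurrentTruncating), byte-identical across calls with the same
#'   config.
#' @examples
#' rec <- generateCatalog(syntheticConfig(nNonsilent = 50, seed = 2))
#' head(rec)
#' @export
generateCatalog <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  L <- config@L
  nMis <- as.integer(round(config@missenseFraction * config@nNonsilent))
  nTrunc <- config@nNonsilent - nMis
  nSilent <- as.integer(round(config@silentRatio * config@nNonsilent))
  f <- config@enrichmentFactor
  withSeed(config@seed, {
    posMis <- if (config@enrichTruncating)
      sample.int(L, nMis, replace = TRUE) else
      .sampleEnriched(nMis, L, config@domain, f)
    posTrunc <- if (config@enrichTruncating)
      .sampleEnriched(nTrunc, L, config@domain, f) else
      sample.int(L, nTrunc, replace = TRUE)
    posSilent <- if (nSilent > 0L)
      sample.int(L, nSilent, replace = TRUE) else integer(0)
    labMis <- sample(.TCGA_MISSENSE, nMis, replace = TRUE,
                     prob = c(0.90, 0.05, 0.05))
    labTrunc <- sample(.TCGA_TRUNCATING, nTrunc, replace = TRUE,
                       prob = c(0.30, 0.35, 0.15, 0.20))
    position <- c(posMis, posTrunc, posSilent)
    rawLabel <- c(labMis, labTrunc, rep("Silent", nSilent))
    class <- rep(c("missense", "truncating", "silent"),
                 c(nMis, nTrunc, nSilent))
    occ <- stats::ave(seq_along(position), paste(class, position),
                      FUN = seq_along)
    token <- .synthToken(position, class, occ)
    nRec <- length(position)
    shallow <- rep(FALSE, nRec)
    if (nMis > 0L)
      shallow[seq_len(nMis)] <-
        stats::runif(nMis) < config@concurrentLossProb
    if (config@duplicationRate > 0 && nRec > 1L) {
      nDup <- as.integer(floor(config@duplicationRate * nRec))
      if (nDup > 0L) {
        tgt <- sample.int(nRec - 1L, nDup, replace = TRUE) + 1L
        src <- vapply(tgt, function(i) sample.int(i - 1L, 1L), 1L)
        position[tgt] <- position[src]
        rawLabel[tgt] <- rawLabel[src]
        token[tgt] <- token[src]
        class[tgt] <- class[src]
      }
    }
    data.frame(
      caseId = sprintf("SYN-%05d", seq_len(nRec)),
      position = as.integer(position),
      rawLabel = rawLabel,
      proteinChange = token,
      shallowDeletion = shallow,
      concurrentTruncating = rep(FALSE, nRec),
      stringsAsFactors = FALSE)
  })
}

#' Cohort background frequency matching a synthetic config
#'
#' Per-aa non-synonymous mutation frequency consistent with the catalogs a
#' config generates, for use as the background of [geneBurdenTest()]. For a
#' uniform config (factor 1) this is \code{nNonsilent / L}; for an enriched
#' config the background is computed from the expected outside-domain
#' counts only (and flagged as such), since the enriched interval does not
#' represent the cohort-wide rate.
#'
#' @param config a [SyntheticConfig-class].
#' @return list with \code{frequency} (per-aa), \code{basis} ("uniform" or
#'   "outside_domain"), \code{L} and \code{nNonsilent}.
#' @export
generateCohortBackground <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  if (config@nNonsilent == 0L)
    stop("degenerate background: config generates no non-silent mutations",
         call. = FALSE)
  L <- config@L
  f <- config@enrichmentFactor
  nMis <- as.integer(round(config@missenseFraction * config@nNonsilent))
  nTrunc <- config@nNonsilent - nMis
  if (f == 1) {
    list(frequency = config@nNonsilent / L, basis = "uniform",
         L = L, nNonsilent = config@nNonsilent)
  } else {
    w <- domainWidth(config@domain)
    out <- L - w
    pOutEnriched <- out / (f * w + out)
    pOutUniform <- out / L
    expectedOutside <- if (config@enrichTruncating)
      nMis * pOutUniform + nTrunc * pOutEnriched
    else
      nMis * pOutEnriched + nTrunc * pOutUniform
    list(frequency = expectedOutside / out, basis = "outside_domain",
         L = L, nNonsilent = config@nNonsilent)
  }
}

#' Write a synthetic catalog as a MAF-dialect TSV
#'
#' Emits records (typically from [generateCatalog()]) as a tab-separated
#' table readable by [readMaf()] with the default TCGA dialect plus a
#' shallow-deletion flag column, and optionally a JSON sidecar recording
#' the generating config.
#'
#' @param records record data.frame.
#' @param path output TSV path.
#' @param config optional [SyntheticConfig-class]; when given, a
#'   \code{<path>.config.json} sidecar is written.
#' @return \code{path}, invisibly.
#' @export
writeMaf <- function(records, path, config = NULL) {
  out <- data.frame(
    Tumor_Sample_Barcode = records$caseId,
    Protein_position = records$position,
    HGVSp_Short = records$proteinChange,
    Variant_Classification = records$rawLabel,
    Shallow_Deletion = as.integer(records$shallowDeletion),
    Concurrent_Truncating = as.integer(records$concurrentTruncating),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(config)) {
    stopifnot(is(config, "SyntheticConfig"))
    jsonlite::write_json(
      list(L = config@L, nNonsilent = config@nNonsilent,
           missenseFraction = config@missenseFraction,
           domain = list(name = config@domain@name,
                         start = config@domain@start,
                         end = config@domain@end),
           enrichmentFactor = config@enrichmentFactor,
           silentRatio = config@silentRatio,
           concurrentLossProb = config@concurrentLossProb,
           duplicationRate = config@duplicationRate,
           enrichTruncating = config@enrichTruncating,
           seed = config@seed),
      paste0(path, ".config.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(path)
}

#' Dialect matching [writeMaf()] output
#'
#' @return a [mafDialect()] whose column names match the TSVs written by
#'   [writeMaf()], including the concurrent-loss flag columns.
#' @export
syntheticDialect <- function() {
  mafDialect(case = "Tumor_Sample_Barcode", position = "Protein_position",
             proteinChange = "HGVSp_Short",
             label = "Variant_Classification",
             shallowDeletion = "Shallow_Deletion",
             concurrentTruncating = "Concurrent_Truncating")
}
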