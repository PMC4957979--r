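#' @import methods
NULL

MUTATION_CLASSES <- c("missense", "truncating", "silent", "other")

.RECORD_COLS <- c("caseId", "position", "rawLabel", "proteinChange",
                  "shallowDeletion", "concurrentTruncating")

#' DomainSpec: a named closed interval on protein coordinates
#'
#' Represents a protein domain as a closed interval \code{[start, end]} of
#' 1-based amino-acid positions. All coordinates in this package are 1-based
#' and inclusive on the full-length polypeptide (for ATM, residues 1-3057
#' including the stop codon).
#'
#' @slot name character(1), a label for the domain.
#' @slot start integer(1), first residue of the interval (1-based).
#' @slot end integer(1), last residue of the interval, \code{end >= start}.
#'
#' @seealso [domainSpec()], [kinaseDomain()]
#' @export
setClass("DomainSpec",
  slots = c(name = "character", start = "integer", end = "integer"))

setValidity("DomainSpec", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@start) != 1L || length(object@end) != 1L)
    return("'start' and 'end' must be single integers")
  if (is.na(object@start) || is.na(object@end))
    return("'start' and 'end' must not be NA")
  if (object@start < 1L)
    return("'start' must be >= 1")
  if (object@end < object@start)
    return("'end' must be >= 'start'")
  TRUE
})

#' ClassifiedCatalog: classified, deduplicated mutation catalog
#'
#' Holds the per-call records of a mutation catalog together with the
#' deduplicated unique protein-level mutations, partitioned into the four
#' mutation classes (missense, truncating, silent, other). Built by
#' [classifyCatalog()] or [deduplicateUnique()].
#'
#' @slot records data.frame of individual calls: \code{caseId},
#'   \code{position}, \code{rawLabel}, \code{proteinChange}, \code{class},
#'   \code{shallowDeletion}, \code{concurrentTruncating}.
#' @slot uniques data.frame of unique mutations (one row per distinct
#'   (proteinChange, class) key): \code{proteinChange}, \code{position},
#'   \code{class}, \code{rawLabel} (first seen), \code{shallowDeletion} and
#'   \code{concurrentTruncating} (OR over the carrying cases), \code{nCases}.
#' @slot L integer(1), protein length in amino acids (default 3057 for ATM,
#'   including the stop codon).
#' @slot dialect character(1), the label vocabulary the catalog was
#'   classified under ("tcga" or "lovd").
#' @slot log list of run metadata: per-class counts, label mapping table,
#'   quarantined rows, whether concurrent-loss information is available.
#'
#' @seealso [classifyCatalog()], [uniqueMutations()], [classCounts()]
#' @export
setClass("ClassifiedCatalog",
  slots = c(records = "data.frame", uniques = "data.frame",
            L = "integer", dialect = "character", log = "list"))

setValidity("ClassifiedCatalog", function(object) {
  if (length(object@L) != 1L || is.na(object@L) || object@L < 1L)
    return("'L' must be a single positive integer")
  u <- object@uniques
  need <- c("proteinChange", "position", "class")
  if (!all(need %in% names(u)))
    return(sprintf("'uniques' must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(u)) {
    if (!all(u$class %in% MUTATION_CLASSES))
      return("unique mutation classes must be missense/truncating/silent/other")
    if (anyDuplicated(paste(u$proteinChange, u$class, sep = "\r")))
      return("'uniques' contains duplicated (proteinChange, class) keys")
    if (any(u$position < 1L | u$position > object@L))
      return("unique mutation positions must lie in [1, L]")
  }
  TRUE
})

#' DensityProfile: per-residue mutation density with fold-change bands
#'
#' Result container of [densityProfile()]: raw per-position unique-mutation
#' counts, the Gaussian-kernel smoothed density, the expected per-position
#' frequency under the null model, the fold change and its
#' Bonferroni-corrected Clopper-Pearson confidence band.
#'
#' @slot position integer vector \code{1:L}.
#' @slot y integer vector, observed unique-mutation count per residue.
#' @slot yHat numeric vector, kernel-smoothed counts.
#' @slot expected numeric vector, expected per-position frequency.
#' @slot fold numeric vector, \code{yHat/expected} (Inf where expected is 0
#'   but yHat > 0; NA where both are 0).
#' @slot ciLow,ciHigh numeric vectors, fold-scale confidence bounds.
#' @slot n integer(1), unique mutations of the class (binomial trials).
#' @slot b numeric(1), kernel window size in aa.
#' @slot mutClass character(1), "missense" or "truncating".
#' @slot alpha numeric(1), family-wise level before correction.
#' @slot mTests numeric(1), Bonferroni divisor (number of corrected tests).
#' @slot expectedMode character(1), "uniform" or "silent_calibrated".
#'
#' @export
setClass("DensityProfile",
  slots = c(position = "integer", y = "integer", yHat = "numeric",
            expected = "numeric", fold = "numeric",
            ciLow = "numeric", ciHigh = "numeric",
            n = "integer", b = "numeric", mutClass = "character",
            alpha = "numeric", mTests = "numeric", expectedMode = "character"))

setValidity("DensityProfile", function(object) {
  L <- length(object@position)
  lens <- c(length(object@y), length(object@yHat), length(object@expected),
            length(object@fold), length(object@ciLow), length(object@ciHigh))
  if (any(lens != L))
    return("all per-position vectors must have the same length")
  if (any(object@y < 0L))
    return("'y' must be non-negative")
  if (sum(object@y) != object@n)
    return("sum(y) must equal n")
  if (any(object@yHat < -1e-9))
    return("'yHat' must be non-negative")
  if (object@b <= 0)
    return("'b' must be positive")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must be in (0, 1)")
  ok <- is.finite(object@fold) & is.finite(object@ciLow) &
        is.finite(object@ciHigh)
  if (any(object@ciLow[ok] > object@fold[ok] + 1e-9) ||
      any(object@ciHigh[ok] < object@fold[ok] - 1e-9))
    return("confidence band must bracket the fold estimate")
  TRUE
})

#' DomainEnrichmentResult: permutation test of in-domain mutation count
#'
#' Result of [domainPermutationTest()]: the observed number of unique
#' mutations in a domain, the mean in-domain count under the uniform
#' permutation null, the enrichment fold, the in/out rate ratio, and the
#' add-one empirical upper-tail p-value.
#'
#' @slot observed integer(1), unique mutations inside the domain.
#' @slot expectedMean numeric(1), mean permuted in-domain count.
#' @slot fold numeric(1), \code{observed/expectedMean}.
#' @slot rateRatio numeric(1), (observed/width) / ((n-observed)/(L-width)):
#'   the per-residue mutation rate inside the domain relative to outside.
#' @slot pValue numeric(1), add-one empirical upper-tail probability,
#'   always in (0, 1].
#' @slot nPerm integer(1), permutation replicates.
#' @slot seed integer(1), RNG seed used.
#' @slot n integer(1), unique mutations of the tested class.
#' @slot L integer(1), protein length.
#' @slot domain DomainSpec, the tested interval.
#' @slot mutClass character(1), mutation class tested.
#'
#' @export
setClass("DomainEnrichmentResult",
  slots = c(observed = "integer", expectedMean = "numeric", fold = "numeric",
            rateRatio = "numeric", pValue = "numeric", nPerm = "integer",
            seed = "integer", n = "integer", L = "integer",
            domain = "DomainSpec", mutClass = "character"))

setValidity("DomainEnrichmentResult", function(object) {
  if (object@observed < 0L || object@observed > object@n)
    return("'observed' must lie in [0, n]")
  if (object@pValue <= 0 || object@pValue > 1)
    return("'pValue' must be in (0, 1]")
  if (object@fold < 0)
    return("'fold' must be non-negative")
  if (object@nPerm < 1L)
    return("'nPerm' must be >= 1")
  TRUE
})

#' SyntheticConfig: parameters of the synthetic catalog generator
#'
#' Parameters for [generateCatalog()]. The generator draws missense
#' positions from a piecewise-uniform density with rate proportional to
#' \code{enrichmentFactor} inside \code{domain} and 1 outside; truncating
#' and silent positions are uniform over \code{1:L}.
#'
#' @slot L integer(1), protein length (default 3057).
#' @slot nNonsilent integer(1), number of non-synonymous unique mutations.
#' @slot missenseFraction numeric(1), share of non-silent records labelled
#'   missense (default 206/286).
#' @slot domain DomainSpec, the enriched interval (default residues
#'   2711-2962, the ATM kinase domain).
#' @slot enrichmentFactor numeric(1), multiplicative in-domain rate ratio
#'   applied to missense positions (default 2.5).
#' @slot silentRatio numeric(1), silent:non-silent count ratio (default 0.5).
#' @slot concurrentLossProb numeric(1), probability a missense record is
#'   flagged with a concurrent shallow deletion (default 105/206).
#' @slot duplicationRate numeric(1), fraction of records that repeat an
#'   earlier record's protein change (collapsed by deduplication); default 0.
#' @slot enrichTruncating logical(1), apply the enrichment to truncating
#'   instead of missense positions (negative-control switch).
#' @slot seed integer(1), RNG seed; the generator is a pure function of
#'   (config, seed).
#'
#' @seealso [syntheticConfig()], [generateCatalog()]
#' @export
setClass("SyntheticConfig",
  slots = c(L = "integer", nNonsilent = "integer",
            missenseFraction = "numeric", domain = "DomainSpec",
            enrichmentFactor = "numeric", silentRatio = "numeric",
            concurrentLossProb = "numeric", duplicationRate = "numeric",
            enrichTruncating = "logical", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@L < 1L) return("'L' must be >= 1")
  if (object@nNonsilent < 0L) return("'nNonsilent' must be >= 0")
  if (object@missenseFraction < 0 || object@missenseFraction > 1)
    return("'missenseFraction' must be in [0, 1]")
  if (object@enrichmentFactor <= 0)
    return("'enrichmentFactor' must be > 0")
  if (object@silentRatio < 0) return("'silentRatio' must be >= 0")
  if (object@concurrentLossProb < 0 || object@concurrentLossProb > 1)
    return("'concurrentLossProb' must be in [0, 1]")
  if (object@duplicationRate < 0 || object@duplicationRate > 1)
    return("'duplicationRate' must be in [0, 1]")
  if (object@domain@end > object@L)
    return("'domain' must lie within [1, L]")
  TRUE
})

# ---- show methods ----

#' @export
setMethod("show", "DomainSpec", function(object) {
  cat(sprintf("DomainSpec '%s': residues %d-%d (%d aa)\n",
              object@name, object@start, object@end,
              object@end - object@start + 1L))
})

#' @export
setMethod("show", "ClassifiedCatalog", function(object) {
  cc <- classCounts(object, unique = TRUE)
  cat(sprintf("ClassifiedCatalog (%s dialect), protein length %d aa\n",
              object@dialect, object@L))
  cat(sprintf("  %d records, %d unique mutations\n",
              nrow(object@records), nrow(object@uniques)))
  cat(sprintf("  unique: %s\n",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", ")))
  q <- object@log$quarantine
  if (!is.null(q) && nrow(q))
    cat(sprintf("  %d row(s) quarantined (see catalogLog())\n", nrow(q)))
})

#' @export
setMethod("show", "DensityProfile", function(object) {
  cat(sprintf("DensityProfile: %s, L = %d, b = %g aa, n = %d uniques\n",
              object@mutClass, length(object@position), object@b, object@n))
  cat(sprintf("  expected model: %s; alpha = %g, Bonferroni m = %g\n",
              object@expectedMode, object@alpha, object@mTests))
  fmax <- suppressWarnings(max(object@fold[is.finite(object@fold)]))
  if (is.finite(fmax))
    cat(sprintf("  max fold %.3f at residue %d\n", fmax,
                object@position[which.max(replace(object@fold,
                  !is.finite(object@fold), -Inf))]))
})

#' @export
setMethod("show", "DomainEnrichmentResult", function(object) {
  cat(sprintf("DomainEnrichmentResult: %s in '%s' [%d-%d]\n",
              object@mutClass, object@domain@name,
              object@domain@start, object@domain@end))
  cat(sprintf("  observed %d / expected %.2f of n = %d uniques (L = %d)\n",
              object@observed, object@expectedMean, object@n, object@L))
  cat(sprintf("  fold = %.3f, in/out rate ratio = %.3f, p = %.3g (%d perms, seed %d)\n",
              object@fold, object@rateRatio, object@pValue,
              object@nPerm, object@seed))
})

#' @export
setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: L = %d, %d non-silent (missense fraction %.3f)\n",
              object@L, object@nNonsilent, object@missenseFraction))
  cat(sprintf("  enriched interval %s [%d-%d], factor %g (%s)\n",
              object@domain@name, object@domain@start, object@domain@end,
              object@enrichmentFactor,
              if (object@enrichTruncating) "truncating" else "missense"))
  cat(sprintf("  silent ratio %g, concurrent-loss prob %g, seed %d\n",
              object@silentRatio, object@concurrentLossProb, object@seed))
})
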