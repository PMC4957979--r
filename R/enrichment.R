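#' Construct a DomainSpec
#'
#' @param name domain label.
#' @param start,end 1-based inclusive residue interval.
#' @return A [DomainSpec-class].
#' @examples
#' domainSpec("FATC", 3029, 3056)
#' kinaseDomain()
#' @export
domainSpec <- function(name, start, end) {
  new("DomainSpec", name = as.character(name),
      start = as.integer(start), end = as.integer(end))
}

#' @rdname domainSpec
#' @details \code{kinaseDomain()} returns the ATM kinase domain, residues
#'   2711-2962, the default interval tested for enrichment.
#' @export
kinaseDomain <- function() domainSpec("kinase", 2711L, 2962L)

#' @rdname domainSpec
#' @param object a [DomainSpec-class].
#' @export
domainWidth <- function(object) object@end - object@start + 1L

# evaluate `expr` under a fixed seed without disturbing the caller's RNG
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Closed-form expected in-domain count under the uniform null
#'
#' The analytic twin of the permutation mean: n mutations placed uniformly
#' on \code{1:L} land in a closed interval of width w with expectation
#' \code{n * w / L}.
#'
#' @param n number of unique mutations.
#' @param domain a [DomainSpec-class].
#' @param L protein length in aa.
#' @return expected in-domain count (numeric scalar).
#' @examples
#' closedFormExpected(206, kinaseDomain(), 3057)  # ~16.98
#' @export
closedFormExpected <- function(n, domain = kinaseDomain(), L = 3057L) {
  stopifnot(is(domain, "DomainSpec"))
  n * domainWidth(domain) / L
}

.domainCheck <- function(domain, L) {
  if (domain@start < 1L || domain@end > L)
    stop(sprintf("domain [%d, %d] lies outside the protein [1, %d]",
                 domain@start, domain@end, L), call. = FALSE)
}

#' Permutation test for domain enrichment of unique mutations
#'
#' Tests whether a protein domain carries more unique mutations of a class
#' than expected if mutations fell uniformly along the protein. Each
#' permutation replicate places the n unique mutations independently and
#' uniformly on \code{1:L} and counts how many land in the domain. The
#' empirical upper-tail p-value uses the add-one estimator
#' \code{(1 + #\{permuted >= observed\}) / (1 + nPerm)}, so it is never 0.
#' The result carries two effect sizes: \code{fold}, the observed count
#' over the mean permuted count, and \code{rateRatio}, the per-residue
#' mutation rate inside the domain relative to outside
#' (\code{(obs/w) / ((n-obs)/(L-w))}), which estimates the in/out rate
#' ratio directly.
#'
#' @param catalog a [ClassifiedCatalog-class] (deduplicated).
#' @param class mutation class to test ("missense" or "truncating").
#' @param domain a [DomainSpec-class]; defaults to the ATM kinase domain.
#' @param nPerm number of permutation replicates (default 10000).
#' @param seed RNG seed; the result is a pure function of
#'   (catalog, domain, nPerm, seed).
#' @return A [DomainEnrichmentResult-class].
#' @examples
#' cfg <- syntheticConfig(nNonsilent = 286, seed = 11)
#' cat <- classifyCatalog(generateCatalog(cfg), "tcga")
#' domainPermutationTest(cat, "missense", nPerm = 1000, seed = 1)
#' @export
domainPermutationTest <- function(catalog,
                                  class = c("missense", "truncating"),
                                  domain = kinaseDomain(),
                                  nPerm = 10000L, seed = 1L) {
  stopifnot(is(catalog, "ClassifiedCatalog"), is(domain, "DomainSpec"))
  class <- match.arg(class)
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L)
    stop("'nPerm' must be >= 1", call. = FALSE)
  L <- proteinLength(catalog)
  .domainCheck(domain, L)
  pos <- uniqueMutations(catalog, class)$position
  n <- length(pos)
  if (n == 0L)
    stop(sprintf("empty class: catalog has no unique %s mutations", class),
         call. = FALSE)
  observed <- sum(pos >= domain@start & pos <= domain@end)
  w <- domainWidth(domain)
  counts <- withSeed(seed, {
    # chunked so nPerm = 1e5, n = several hundred stays within memory
    chunk <- max(1L, min(nPerm, as.integer(2e7 %/% n)))
    starts <- seq.int(1L, nPerm, by = chunk)
    unlist(lapply(starts, function(s) {
      m <- min(chunk, nPerm - s + 1L)
      draw <- sample.int(L, n * m, replace = TRUE)
      colSums(matrix(draw >= domain@start & draw <= domain@end, n, m))
    }), use.names = FALSE)
  })
  expectedMean <- mean(counts)
  pValue <- (1 + sum(counts >= observed)) / (1 + nPerm)
  rateRatio <- if (observed == n) Inf else
    (observed / w) / ((n - observed) / (L - w))
  new("DomainEnrichmentResult",
      observed = as.integer(observed), expectedMean = expectedMean,
      fold = if (expectedMean > 0) observed / expectedMean else NaN,
      rateRatio = rateRatio, pValue = pValue, nPerm = nPerm,
      seed = as.integer(seed), n = as.integer(n), L = as.integer(L),
      domain = domain, mutClass = class)
}

#' Gene-level mutation burden test against a cohort background
#'
#' Asks whether a gene carries more (or fewer) non-synonymous mutations
#' than expected from its size and the cohort-wide per-residue mutation
#' frequency ("is the gene hyper-mutated?"). The null is configurable:
#' \code{poisson} draws counts from Poisson(background x length);
#' \code{binomial} draws from Binomial(total cohort mutations, gene length
#' share of the total length). The empirical p-value is two-sided
#' (doubled smaller tail, add-one smoothed, capped at 1). The background
#' frequency must be supplied by the caller - the test is relative by
#' construction and the package embeds no cohort data.
#'
#' @param observed observed non-synonymous mutation count in the gene.
#' @param geneLengthAa gene length in amino acids.
#' @param background per-aa non-synonymous mutation frequency of the
#'   cohort (required for the poisson null), e.g. from
#'   [generateCohortBackground()].
#' @param nPerm permutation replicates (default 10000).
#' @param seed RNG seed.
#' @param null "poisson" (default) or "binomial".
#' @param totalMutations,totalLengthAa cohort totals, required for the
#'   binomial null.
#' @return list with \code{observed}, \code{expectedMean}, \code{fold},
#'   \code{pValue}, \code{null}, \code{nPerm}, \code{seed}.
#' @examples
#' geneBurdenTest(60, 3057, background = 0.02, nPerm = 2000, seed = 1)
#' @export
geneBurdenTest <- function(observed, geneLengthAa, background = NULL,
                           nPerm = 10000L, seed = 1L,
                           null = c("poisson", "binomial"),
                           totalMutations = NULL, totalLengthAa = NULL) {
  null <- match.arg(null)
  nPerm <- as.integer(nPerm)
  if (is.na(nPerm) || nPerm < 1L)
    stop("'nPerm' must be >= 1", call. = FALSE)
  draws <- withSeed(seed, {
    if (null == "poisson") {
      if (is.null(background) || !is.numeric(background) || background <= 0)
        stop("gene burden is relative by construction: supply a positive ",
             "per-aa 'background' frequency", call. = FALSE)
      stats::rpois(nPerm, background * geneLengthAa)
    } else {
      if (is.null(totalMutations) || is.null(totalLengthAa))
        stop("binomial null needs 'totalMutations' and 'totalLengthAa'",
             call. = FALSE)
      stats::rbinom(nPerm, totalMutations, geneLengthAa / totalLengthAa)
    }
  })
  expectedMean <- mean(draws)
  upper <- (1 + sum(draws >= observed)) / (1 + nPerm)
  lower <- (1 + sum(draws <= observed)) / (1 + nPerm)
  list(observed = observed, expectedMean = expectedMean,
       fold = if (expectedMean > 0) observed / expectedMean else NaN,
       pValue = min(1, 2 * min(upper, lower)),
       pUpper = upper, pLower = lower,
       null = null, nPerm = nPerm, seed = as.integer(seed))
}

#' Serialise enrichment results
#'
#' \code{writeEnrichment} writes one [DomainEnrichmentResult-class] as JSON
#' (observed, expected mean, fold, in/out rate ratio, p, nPerm, seed,
#' domain). \code{enrichmentRow} returns the same fields as a one-row
#' data.frame for multi-domain TSV output.
#'
#' @param result a [DomainEnrichmentResult-class].
#' @param path output JSON path.
#' @return \code{path} (or the data.frame), invisibly.
#' @export
writeEnrichment <- function(result, path) {
  stopifnot(is(result, "DomainEnrichmentResult"))
  jsonlite::write_json(as.list(enrichmentRow(result)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeEnrichment
#' @export
enrichmentRow <- function(result) {
  stopifnot(is(result, "DomainEnrichmentResult"))
  data.frame(domain = result@domain@name, start = result@domain@start,
             end = result@domain@end, class = result@mutClass,
             n = result@n, L = result@L, observed = result@observed,
             expectedMean = result@expectedMean, fold = result@fold,
             rateRatio = result@rateRatio, pValue = result@pValue,
             nPerm = result@nPerm, seed = result@seed,
             stringsAsFactors = FALSE)
}
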