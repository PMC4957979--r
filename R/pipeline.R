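.SPLICE_STOP_LABELS <- c("Splice_Site", "Stop_Codon")

#' Class-fraction table of a catalog
#'
#' Fractions of unique non-synonymous mutations per class. The
#' \code{standard} grouping reports missense / truncating / other as
#' classified by [classifyLabel()]. The \code{spliceStopOther} grouping is a
#' reporting variant that moves splice-site and stop-codon labels out of
#' the truncating class into "Others" (the computation elsewhere in the
#' package always uses the standard classes). Silent mutations are excluded
#' from the denominator.
#'
#' @param catalog a [ClassifiedCatalog-class].
#' @param grouping "standard" (default) or "spliceStopOther".
#' @return data.frame with columns \code{group}, \code{count},
#'   \code{fraction}.
#' @export
reportClassFractions <- function(catalog, grouping = c("standard", "spliceStopOther")) {
  stopifnot(is(catalog, "ClassifiedCatalog"))
  grouping <- match.arg(grouping)
  u <- uniqueMutations(catalog)
  u <- u[u$class != "silent", , drop = FALSE]
  group <- u$class
  if (grouping == "spliceStopOther")
    group[u$rawLabel %in% .SPLICE_STOP_LABELS] <- "other"
  levels <- c("missense", "truncating", "other")
  count <- vapply(levels, function(g) sum(group == g), 0L)
  total <- sum(count)
  data.frame(group = levels, count = count,
             fraction = if (total > 0) count / total else rep(NA_real_, 3L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Configuration of an end-to-end pipeline run
#'
#' Bundles every knob of a classify - density - enrichment run. A run is
#' fully determined by the config plus its inputs; all randomness flows
#' from \code{seed} through per-stage substreams.
#'
#' @param input path to the input TSV, or NULL when \code{records} is
#'   given directly.
#' @param records optional in-memory record data.frame (e.g. from
#'   [generateCatalog()]); used when \code{input} is NULL.
#' @param inputType "maf" or "lovd".
#' @param dialect a [mafDialect()] for MAF input.
#' @param missenseLabels accepted LOVD missense labels, see
#'   [classifyLabel()].
#' @param L protein length in aa.
#' @param classes classes to profile and test.
#' @param b kernel window size in aa.
#' @param domains list of [DomainSpec-class] to test.
#' @param expectedMode,ratio expected-rate model, see [expectedRate()].
#' @param alpha,mTests confidence-band level and Bonferroni divisor
#'   (\code{mTests = NULL} uses L).
#' @param nPerm permutation replicates per enrichment test.
#' @param seed run seed.
#' @param outDir output directory (created if missing).
#' @param filterConcurrent restrict missense to the concurrent-loss subset
#'   before analysis, see [filterConcurrentLoss()].
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(input = NULL, records = NULL,
                      inputType = c("maf", "lovd"),
                      dialect = syntheticDialect(), missenseLabels = NULL,
                      L = 3057L, classes = c("missense", "truncating"),
                      b = 80, domains = list(kinaseDomain()),
                      expectedMode = c("uniform", "silent_calibrated"),
                      ratio = NULL, alpha = 0.05, mTests = NULL,
                      nPerm = 10000L, seed = 1L, outDir = tempfile("run"),
                      filterConcurrent = FALSE) {
  inputType <- match.arg(inputType)
  expectedMode <- match.arg(expectedMode)
  if (is.null(input) && is.null(records))
    stop("runConfig needs an 'input' path or in-memory 'records'",
         call. = FALSE)
  classes <- match.arg(classes, c("missense", "truncating"),
                       several.ok = TRUE)
  stopifnot(all(vapply(domains, is, logical(1), "DomainSpec")))
  structure(list(input = input, records = records, inputType = inputType,
                 dialect = dialect, missenseLabels = missenseLabels,
                 L = as.integer(L), classes = classes, b = b,
                 domains = domains, expectedMode = expectedMode,
                 ratio = ratio, alpha = alpha, mTests = mTests,
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 outDir = outDir, filterConcurrent = filterConcurrent),
            class = "RunConfig")
}

.stage <- function(name, outDir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(outDir, "PARTIAL")
    try(writeLines(sprintf("failed at stage: %s", name), marker),
        silent = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full classify - density - enrichment pipeline
#'
#' Reads (or receives) a mutation catalog, classifies and deduplicates it,
#' writes the classification report and class-fraction tables, computes the
#' per-class density profiles with confidence bands, runs the domain
#' permutation tests, and writes a manifest with the seed and md5 checksums
#' of every emitted file. Re-running with the same config and inputs
#' reproduces byte-identical outputs. A class with no unique mutations is
#' skipped with a logged reason instead of failing the run.
#'
#' @param config a [runConfig()].
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}): input summary, per-class fractions, density
#'   and enrichment summaries, output checksums.
#' @examples
#' cfg <- syntheticConfig(nNonsilent = 120, seed = 5)
#' man <- runPipeline(runConfig(records = generateCatalog(cfg),
#'                              nPerm = 500, seed = 5))
#' man$enrichment
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(outDir, "PARTIAL"))

  records <- .stage("read", outDir, {
    if (!is.null(config$input)) {
      if (config$inputType == "maf")
        readMaf(config$input, config$dialect, L = config$L)
      else
        readVariantList(config$input, L = config$L)
    } else config$records
  })

  catalog <- .stage("classify", outDir, {
    dialectName <- if (config$inputType == "lovd") "lovd" else "tcga"
    cat <- classifyCatalog(records, dialect = dialectName, L = config$L,
                           missenseLabels = config$missenseLabels)
    if (config$filterConcurrent) cat <- filterConcurrentLoss(cat)
    writeCatalog(cat, file.path(outDir, "classified_catalog.tsv"))
    writeRunReport(cat, file.path(outDir, "classification_report.json"))
    cat
  })

  fractions <- .stage("fractions", outDir, {
    fr <- list(standard = reportClassFractions(catalog, "standard"),
               spliceStopOther = reportClassFractions(catalog, "spliceStopOther"))
    utils::write.table(
      cbind(grouping = rep(names(fr), each = 3L),
            do.call(rbind, fr)),
      file.path(outDir, "class_fractions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    fr
  })

  skipped <- list()
  profiles <- list()
  for (cl in config$classes) {
    n <- sum(uniqueMutations(catalog)$class == cl)
    if (n == 0L) {
      skipped[[cl]] <- sprintf(
        "density and enrichment skipped: no unique %s mutations", cl)
      next
    }
    profiles[[cl]] <- .stage(paste0("density_", cl), outDir, {
      pr <- densityProfile(catalog, cl, b = config$b,
                           mode = config$expectedMode,
                           ratio = config$ratio, alpha = config$alpha,
                           mTests = config$mTests)
      writeDensityProfile(pr, file.path(outDir,
                                        sprintf("density_%s.tsv", cl)))
      pr
    })
  }

  enrichment <- .stage("enrichment", outDir, {
    rows <- list()
    k <- 0L
    for (cl in intersect(config$classes, names(profiles))) {
      for (dom in config$domains) {
        k <- k + 1L
        res <- domainPermutationTest(catalog, cl, dom,
                                     nPerm = config$nPerm,
                                     seed = config$seed + k)
        writeEnrichment(res, file.path(outDir,
          sprintf("enrichment_%s_%s.json", dom@name, cl)))
        rows[[k]] <- enrichmentRow(res)
      }
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      utils::write.table(tab, file.path(outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      tab
    } else data.frame()
  })

  manifest <- .stage("manifest", outDir, {
    files <- setdiff(list.files(outDir), c("manifest.json", "PARTIAL"))
    man <- list(
      package = "MutHotspot",
      version = as.character(utils::packageVersion("MutHotspot")),
      seed = config$seed,
      L = config$L,
      input = if (is.null(config$input)) "in-memory records"
        else config$input,
      inputType = config$inputType,
      nRecords = nrow(mutationRecords(catalog)),
      nUnique = nrow(uniqueMutations(catalog)),
      uniqueCounts = as.list(classCounts(catalog)),
      classFractions = fractions,
      skipped = skipped,
      enrichment = enrichment,
      outputs = lapply(files, function(f) list(
        file = f,
        md5 = unname(tools::md5sum(file.path(outDir, f))))))
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
    man
  })
  invisible(manifest)
}
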