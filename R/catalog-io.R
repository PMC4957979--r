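#' Column-name dialect for MAF-like tables
#'
#' Declares which columns of a tab-separated variant table hold the case
#' identifier, the protein position (or a protein-change token such as
#' \code{p.N2875K} from which the position is extracted), the variant-class
#' label, and the optional concurrent copy-number / truncation flags.
#'
#' @param case column holding the case/sample identifier, or NULL if absent.
#' @param position column holding the amino-acid position; may contain
#'   \code{p.}-style tokens, in which case the first integer is extracted.
#' @param proteinChange column holding the protein-change token used as the
#'   uniqueness key. When NULL, the position column's token is reused.
#' @param label column holding the raw variant-class label.
#' @param shallowDeletion,concurrentTruncating optional logical (or 0/1)
#'   columns flagging concurrent shallow deletion / concurrent truncating
#'   mutation in the same case; NULL if the table has no such columns.
#'
#' @return A list of class \code{MafDialect}.
#' @examples
#' mafDialect(case = "sample", position = "aa_pos", label = "effect")
#' @export
mafDialect <- function(case = "Tumor_Sample_Barcode",
                       position = NULL,
                       proteinChange = "HGVSp_Short",
                       label = "Variant_Classification",
                       shallowDeletion = NULL,
                       concurrentTruncating = NULL) {
  if (is.null(position) && is.null(proteinChange))
    stop("dialect must name a 'position' or a 'proteinChange' column",
         call. = FALSE)
  if (is.null(label))
    stop("dialect must name a 'label' column", call. = FALSE)
  structure(list(case = case, position = position,
                 proteinChange = proteinChange, label = label,
                 shallowDeletion = shallowDeletion,
                 concurrentTruncating = concurrentTruncating),
            class = "MafDialect")
}

#' @rdname mafDialect
#' @export
tcgaDialect <- function() mafDialect()

#' Extract the amino-acid position from a protein-change token
#'
#' Takes the first run of digits in tokens like \code{p.N2875K},
#' \code{p.K2717fs*10} or plain \code{"2875"}. Tokens without digits give NA.
#'
#' @param token character vector of protein-change tokens.
#' @return integer vector of positions (NA where no digits are present).
#' @examples
#' extractPosition(c("p.N2875K", "p.S1981fs", "100", "p.?"))
#' @export
extractPosition <- function(token) {
  token <- as.character(token)
  m <- regmatches(token, regexpr("[0-9]+", token))
  out <- rep(NA_integer_, length(token))
  has <- regexpr("[0-9]+", token) > 0L
  out[has] <- suppressWarnings(as.integer(m))
  out
}

.emptyRecords <- function() {
  data.frame(caseId = character(), position = integer(),
             rawLabel = character(), proteinChange = character(),
             shallowDeletion = logical(), concurrentTruncating = logical(),
             stringsAsFactors = FALSE)
}

.asFlag <- function(x, nrow) {
  if (is.null(x)) return(rep(FALSE, nrow))
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  x %in% c("1", "true", "t", "yes", "y")
}

.quarantineSplit <- function(records, L, rowId) {
  bad <- is.na(records$position) | records$position < 1L | records$position > L
  reason <- ifelse(is.na(records$position), "unparsable position",
                   sprintf("position outside [1, %d]", L))
  quarantine <- cbind(row = rowId[bad], records[bad, , drop = FALSE],
                      reason = reason[bad])
  rownames(quarantine) <- NULL
  good <- records[!bad, , drop = FALSE]
  rownames(good) <- NULL
  attr(good, "quarantine") <- quarantine
  good
}

#' Read a MAF-like tab-separated mutation table
#'
#' Reads one row per mutation call from a tab-separated table with a header,
#' mapping columns through a [mafDialect()]. Rows whose position cannot be
#' parsed or falls outside \code{[1, L]} are quarantined into a side report
#' (attribute \code{"quarantine"} of the result) rather than dropped
#' silently or aborting the run. Row order is preserved.
#'
#' @param path path to the TSV file.
#' @param dialect a [mafDialect()]; defaults to TCGA/firehose column names.
#' @param L protein length in aa used for position validation (default 3057).
#' @return data.frame of mutation records (columns \code{caseId},
#'   \code{position}, \code{rawLabel}, \code{proteinChange},
#'   \code{shallowDeletion}, \code{concurrentTruncating}) with a
#'   \code{"quarantine"} attribute holding the rejected rows and reasons.
#' @seealso [readVariantList()], [classifyCatalog()]
#' @export
readMaf <- function(path, dialect = tcgaDialect(), L = 3057L) {
  stopifnot(inherits(dialect, "MafDialect"))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, quote = "",
                           comment.char = "#")
  posCol <- if (is.null(dialect$position)) dialect$proteinChange else
    dialect$position
  mandatory <- c(position = posCol, label = dialect$label)
  missing <- mandatory[!mandatory %in% names(tab)]
  if (length(missing))
    stop(sprintf("input '%s' lacks mandatory column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  n <- nrow(tab)
  if (n == 0L) return(.emptyRecords())
  caseId <- if (!is.null(dialect$case) && dialect$case %in% names(tab))
    tab[[dialect$case]] else rep("", n)
  pcCol <- dialect$proteinChange
  proteinChange <- if (!is.null(pcCol) && pcCol %in% names(tab))
    trimws(tab[[pcCol]]) else trimws(tab[[posCol]])
  posRaw <- trimws(tab[[posCol]])
  position <- suppressWarnings(as.integer(posRaw))
  needExtract <- is.na(position) & nzchar(posRaw)
  position[needExtract] <- extractPosition(posRaw[needExtract])
  records <- data.frame(
    caseId = as.character(caseId),
    position = position,
    rawLabel = trimws(tab[[dialect$label]]),
    proteinChange = proteinChange,
    shallowDeletion = .asFlag(
      if (!is.null(dialect$shallowDeletion) &&
          dialect$shallowDeletion %in% names(tab))
        tab[[dialect$shallowDeletion]] else NULL, n),
    concurrentTruncating = .asFlag(
      if (!is.null(dialect$concurrentTruncating) &&
          dialect$concurrentTruncating %in% names(tab))
        tab[[dialect$concurrentTruncating]] else NULL, n),
    stringsAsFactors = FALSE)
  out <- .quarantineSplit(records, L, seq_len(n))
  attr(out, "hasFlagColumns") <-
    (!is.null(dialect$shallowDeletion) &&
       dialect$shallowDeletion %in% names(tab)) ||
    (!is.null(dialect$concurrentTruncating) &&
       dialect$concurrentTruncating %in% names(tab))
  out
}

#' Read a LOVD-style germline variant list
#'
#' Reads a two-plus-column tab-separated table: a position (or
#' protein-change token) column and an effect-label column, as exported from
#' locus-specific germline databases. Records carry an empty case identifier.
#'
#' @param path path to the TSV file.
#' @param L protein length in aa for position validation (default 3057).
#' @param positionCol,labelCol column names; by default the first column is
#'   the position/token and the second the effect label.
#' @return data.frame of mutation records as in [readMaf()], with a
#'   \code{"quarantine"} attribute.
#' @export
readVariantList <- function(path, L = 3057L,
                            positionCol = NULL, labelCol = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 2L)
    stop(sprintf("variant list '%s' needs at least two columns", path),
         call. = FALSE)
  if (is.null(positionCol)) positionCol <- names(tab)[1L]
  if (is.null(labelCol)) labelCol <- names(tab)[2L]
  missing <- setdiff(c(positionCol, labelCol), names(tab))
  if (length(missing))
    stop(sprintf("variant list '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  n <- nrow(tab)
  if (n == 0L) return(.emptyRecords())
  tok <- trimws(tab[[positionCol]])
  position <- suppressWarnings(as.integer(tok))
  needExtract <- is.na(position) & nzchar(tok)
  position[needExtract] <- extractPosition(tok[needExtract])
  records <- data.frame(
    caseId = rep("", n),
    position = position,
    rawLabel = trimws(tab[[labelCol]]),
    proteinChange = tok,
    shallowDeletion = rep(FALSE, n),
    concurrentTruncating = rep(FALSE, n),
    stringsAsFactors = FALSE)
  .quarantineSplit(records, L, seq_len(n))
}

# label vocabularies ---------------------------------------------------------

.TCGA_MISSENSE <- c("Missense_Mutation", "In_Frame_Del", "In_Frame_Ins")
.TCGA_TRUNCATING <- c("Nonsense_Mutation", "Frame_Shift_Del",
                      "Frame_Shift_Ins", "Splice_Site")
.TCGA_SILENT <- "Silent"
.LOVD_TRUNCATING <- c("Start_Codon", "Frame_Shift_Del", "Large_DEL",
                      "Nonsense_Mutation", "Frame_Shift_Ins", "Splice_Site",
                      "Stop_Codon")
.LOVD_MISSENSE_DEFAULT <- c("Missense", "Missense_Mutation",
                            "In_Frame_Del", "In_Frame_Ins")
.LOVD_SILENT <- c("Silent", "Synonymous")

#' Map raw variant labels to mutation classes
#'
#' Total, deterministic mapping from a raw variant-class label to one of
#' \code{missense}, \code{truncating}, \code{silent}, \code{other}.
#' Comparison is exact on the token after whitespace trimming.
#'
#' Under the \code{tcga} dialect, \code{Missense_Mutation},
#' \code{In_Frame_Del} and \code{In_Frame_Ins} map to missense;
#' \code{Nonsense_Mutation}, \code{Frame_Shift_Del}, \code{Frame_Shift_Ins}
#' and \code{Splice_Site} to truncating; \code{Silent} to silent. Under the
#' \code{lovd} dialect, \code{Start_Codon}, \code{Frame_Shift_Del},
#' \code{Large_DEL}, \code{Nonsense_Mutation}, \code{Frame_Shift_Ins},
#' \code{Splice_Site} and \code{Stop_Codon} map to truncating, and
#' substitution-effect labels (configurable via \code{missenseLabels}, since
#' LOVD exports vary) to missense. Everything else maps to \code{other}.
#'
#' @param label character vector of raw labels.
#' @param dialect "tcga" or "lovd".
#' @param missenseLabels for the lovd dialect, the accepted missense-effect
#'   labels; defaults to \code{Missense}, \code{Missense_Mutation},
#'   \code{In_Frame_Del}, \code{In_Frame_Ins}.
#' @return character vector of classes, same length as \code{label}.
#' @examples
#' classifyLabel(c("Missense_Mutation", "Splice_Site", "Nonstop_Mutation"),
#'               "tcga")
#' classifyLabel("Large_DEL", "lovd")
#' @export
classifyLabel <- function(label, dialect = c("tcga", "lovd"),
                          missenseLabels = NULL) {
  dialect <- match.arg(dialect)
  label <- trimws(as.character(label))
  if (dialect == "tcga") {
    missense <- .TCGA_MISSENSE
    truncating <- .TCGA_TRUNCATING
    silent <- .TCGA_SILENT
  } else {
    missense <- if (is.null(missenseLabels)) .LOVD_MISSENSE_DEFAULT
      else missenseLabels
    truncating <- .LOVD_TRUNCATING
    silent <- .LOVD_SILENT
  }
  out <- rep("other", length(label))
  out[label %in% missense] <- "missense"
  out[label %in% truncating] <- "truncating"
  out[label %in% silent] <- "silent"
  out
}

.labelMapTable <- function(labels, classes) {
  if (!length(labels))
    return(data.frame(rawLabel = character(), class = character(),
                      n = integer(), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(rawLabel = labels, class = classes),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "n"
  tab <- tab[order(tab$rawLabel), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Deduplicate classified records into unique mutations
#'
#' Collapses classified mutation records to unique protein-level mutations.
#' The uniqueness key is the (protein-change token, class) pair; records
#' sharing a key become one unique mutation whose concurrent-loss flags are
#' the OR over the carrying cases. Records lacking a protein-change token
#' fall back to the (position, raw label) key with a logged notice. When
#' case identifiers are present, a missense record is additionally flagged
#' \code{concurrentTruncating} if the same case carries a truncating record.
#'
#' @param records classified record data.frame (needs a \code{class}
#'   column; see [classifyCatalog()] for the one-step path).
#' @param L protein length in aa (default 3057).
#' @param dialect label vocabulary the records were classified under
#'   (metadata only).
#' @return A [ClassifiedCatalog-class].
#' @export
deduplicateUnique <- function(records, L = 3057L, dialect = "tcga") {
  if (!"class" %in% names(records))
    stop("records must carry a 'class' column; see classifyCatalog()",
         call. = FALSE)
  L <- as.integer(L)
  log <- list(
    quarantine = attr(records, "quarantine"),
    hasFlagColumns = isTRUE(attr(records, "hasFlagColumns")))
  n <- nrow(records)
  if (n) {
    # per-case cross-reference: cases carrying a truncating call flag their
    # missense calls as concurrent
    withCase <- nzchar(records$caseId)
    truncCases <- unique(records$caseId[withCase &
                                          records$class == "truncating"])
    hit <- withCase & records$class == "missense" &
      records$caseId %in% truncCases
    records$concurrentTruncating <- records$concurrentTruncating | hit
    noToken <- is.na(records$proteinChange) | !nzchar(records$proteinChange)
    if (any(noToken)) {
      records$proteinChange[noToken] <-
        paste0("pos", records$position[noToken], ":",
               records$rawLabel[noToken])
      log$fallbackKeyRows <- which(noToken)
    }
    key <- paste(records$proteinChange, records$class, sep = "\r")
    first <- !duplicated(key)
    idx <- match(key, key[first])
    uniques <- data.frame(
      proteinChange = records$proteinChange[first],
      position = records$position[first],
      class = records$class[first],
      rawLabel = records$rawLabel[first],
      shallowDeletion = as.logical(
        tapply(records$shallowDeletion, idx, any)[as.character(
          seq_len(sum(first)))]),
      concurrentTruncating = as.logical(
        tapply(records$concurrentTruncating, idx, any)[as.character(
          seq_len(sum(first)))]),
      nCases = as.integer(tabulate(idx, sum(first))),
      stringsAsFactors = FALSE)
    rownames(uniques) <- NULL
  } else {
    uniques <- data.frame(proteinChange = character(), position = integer(),
                          class = character(), rawLabel = character(),
                          shallowDeletion = logical(),
                          concurrentTruncating = logical(),
                          nCases = integer(), stringsAsFactors = FALSE)
  }
  log$labelMap <- .labelMapTable(records$rawLabel, records$class)
  log$otherLabels <- sort(unique(records$rawLabel[records$class == "other"]))
  log$uniqueCounts <- vapply(MUTATION_CLASSES,
                             function(cl) sum(uniques$class == cl), 0L)
  log$hasCaseInfo <- n > 0L && any(nzchar(records$caseId))
  attr(records, "quarantine") <- NULL
  attr(records, "hasFlagColumns") <- NULL
  new("ClassifiedCatalog", records = records, uniques = uniques,
      L = L, dialect = dialect, log = log)
}

#' Classify and deduplicate a record collection in one step
#'
#' Adds the mutation class to each record via [classifyLabel()] and
#' deduplicates with [deduplicateUnique()].
#'
#' @inheritParams deduplicateUnique
#' @inheritParams classifyLabel
#' @return A [ClassifiedCatalog-class].
#' @examples
#' rec <- data.frame(caseId = "C1", position = 2875,
#'                   rawLabel = "Missense_Mutation",
#'                   proteinChange = "p.N2875K",
#'                   shallowDeletion = FALSE, concurrentTruncating = FALSE)
#' classifyCatalog(rec, dialect = "tcga")
#' @export
classifyCatalog <- function(records, dialect = c("tcga", "lovd"),
                            L = 3057L, missenseLabels = NULL) {
  dialect <- match.arg(dialect)
  records$class <- classifyLabel(records$rawLabel, dialect, missenseLabels)
  deduplicateUnique(records, L = L, dialect = dialect)
}

#' Restrict a catalog to missense mutations with concurrent ATM loss
#'
#' Keeps the unique missense mutations whose case also shows loss of the
#' second allele: a concurrent shallow (heterozygous) deletion or a
#' concurrent truncating mutation in the same case. Truncating, silent and
#' other unique mutations are unchanged. The subset size is recorded in the
#' catalog log.
#'
#' @param catalog a [ClassifiedCatalog-class] whose records carried flag
#'   columns or case identifiers (otherwise the subset is uncomputable and
#'   an error is raised).
#' @return A [ClassifiedCatalog-class] with the filtered missense list.
#' @export
filterConcurrentLoss <- function(catalog) {
  stopifnot(is(catalog, "ClassifiedCatalog"))
  log <- catalog@log
  if (!isTRUE(log$hasFlagColumns) && !isTRUE(log$hasCaseInfo))
    stop("concurrent-loss subset is uncomputable: the input had neither ",
         "concurrent-loss flag columns nor case identifiers for ",
         "cross-referencing truncating calls", call. = FALSE)
  u <- catalog@uniques
  drop <- u$class == "missense" &
    !(u$shallowDeletion | u$concurrentTruncating)
  kept <- u[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  log$concurrentLossSubset <- sum(kept$class == "missense")
  log$concurrentLossInput <- sum(u$class == "missense")
  log$uniqueCounts <- vapply(MUTATION_CLASSES,
                             function(cl) sum(kept$class == cl), 0L)
  initialize(catalog, uniques = kept, log = log)
}

# accessors ------------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("proteinLength", "ClassifiedCatalog", function(object) object@L)

#' @rdname accessors
#' @export
setMethod("mutationRecords", "ClassifiedCatalog",
          function(object) object@records)

#' @rdname accessors
#' @param class optional mutation class to restrict to.
#' @export
setMethod("uniqueMutations", "ClassifiedCatalog",
  function(object, class = NULL) {
    u <- object@uniques
    if (!is.null(class)) {
      class <- match.arg(class, MUTATION_CLASSES)
      u <- u[u$class == class, , drop = FALSE]
      rownames(u) <- NULL
    }
    u
  })

#' @rdname accessors
#' @param unique count unique mutations (TRUE, default) or raw records.
#' @export
setMethod("classCounts", "ClassifiedCatalog",
  function(object, unique = TRUE) {
    src <- if (unique) object@uniques$class else object@records$class
    vapply(MUTATION_CLASSES, function(cl) sum(src == cl), 0L)
  })

#' @rdname accessors
#' @export
setMethod("catalogLog", "ClassifiedCatalog", function(object) object@log)

#' Write a classified catalog and its run report
#'
#' \code{writeCatalog} writes one row per unique mutation (position, class,
#' protein change, concurrent-loss flags, case count) as TSV.
#' \code{writeRunReport} writes the catalog log (per-class counts,
#' label-mapping table, quarantined rows) as JSON.
#'
#' @param catalog a [ClassifiedCatalog-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
  stopifnot(is(catalog, "ClassifiedCatalog"))
  u <- catalog@uniques
  u <- u[order(u$position, u$class, u$proteinChange), , drop = FALSE]
  utils::write.table(u, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCatalog
#' @export
writeRunReport <- function(catalog, path) {
  stopifnot(is(catalog, "ClassifiedCatalog"))
  log <- catalog@log
  report <- list(
    L = catalog@L,
    dialect = catalog@dialect,
    nRecords = nrow(catalog@records),
    nUnique = nrow(catalog@uniques),
    uniqueCounts = as.list(log$uniqueCounts),
    recordCounts = as.list(classCounts(catalog, unique = FALSE)),
    labelMap = log$labelMap,
    otherLabels = log$otherLabels,
    quarantine = if (is.null(log$quarantine))
      data.frame() else log$quarantine,
    concurrentLossSubset = log$concurrentLossSubset)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
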