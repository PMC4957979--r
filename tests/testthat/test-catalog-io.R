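test_that("readMaf parses MAF-like tables through a column dialect", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample\taa_change\teffect",
    "C1\tp.N2875K\tMissense_Mutation",
    "C2\tp.R250X\tNonsense_Mutation",
    "C3\tp.L100L\tSilent"), tsv)
  dia <- mafDialect(case = "sample", proteinChange = "aa_change",
                    label = "effect")
  rec <- readMaf(tsv, dia)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$rawLabel,
               c("Missense_Mutation", "Nonsense_Mutation", "Silent"))
  # positions extracted from p.-style tokens, row order preserved
  expect_equal(rec$position, c(2875L, 250L, 100L))
  expect_equal(rec$caseId, c("C1", "C2", "C3"))
  # flags default false when the source columns are absent
  expect_false(any(rec$shallowDeletion))
  expect_false(any(rec$concurrentTruncating))
})

test_that("readMaf handles empty input, missing columns and bad rows", {
  dia <- mafDialect(case = "sample", position = "pos", label = "effect")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample\tpos\teffect", empty)
  expect_equal(nrow(readMaf(empty, dia)), 0L)

  noLabel <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpos", "C1\t10"), noLabel)
  expect_error(readMaf(noLabel, dia), "effect")

  dirty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tpos\teffect",
               "C1\t150\tMissense_Mutation",
               "C2\t9999\tMissense_Mutation",
               "C3\t???\tSilent"), dirty)
  rec <- readMaf(dirty, dia, L = 3057)
  expect_equal(nrow(rec), 1L)
  q <- attr(rec, "quarantine")
  expect_equal(nrow(q), 2L)
  expect_setequal(q$row, c(2L, 3L))
  expect_match(q$reason[q$row == 3L], "unparsable")
})

test_that("readVariantList reads LOVD-style two-column lists", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\teffect",
               "2875\tMissense",
               "100\tLarge_DEL",
               "100\tLarge_DEL"), tsv)
  rec <- readVariantList(tsv)
  expect_equal(nrow(rec), 3L)       # duplicates kept; dedup is a later stage
  expect_true(all(rec$caseId == ""))
  expect_equal(rec$position[1], 2875L)
  cat <- classifyCatalog(rec, "lovd")
  expect_equal(uniqueMutations(cat, "truncating")$position, 100L)
  expect_equal(uniqueMutations(cat, "missense")$position, 2875L)
})

test_that("classifyLabel maps both vocabularies and is total", {
  cases <- list(
    list("Missense_Mutation", "tcga", "missense"),
    list("In_Frame_Del", "tcga", "missense"),
    list("In_Frame_Ins", "tcga", "missense"),
    list("Nonsense_Mutation", "tcga", "truncating"),
    list("Frame_Shift_Del", "tcga", "truncating"),
    list("Frame_Shift_Ins", "tcga", "truncating"),
    list("Splice_Site", "tcga", "truncating"),
    list("Silent", "tcga", "silent"),
    list("Nonstop_Mutation", "tcga", "other"),
    list("Translation_Start_Site", "tcga", "other"),
    list("Start_Codon", "lovd", "truncating"),
    list("Large_DEL", "lovd", "truncating"),
    list("Stop_Codon", "lovd", "truncating"),
    list("Splice_Site", "lovd", "truncating"),
    list("Missense", "lovd", "missense"),
    list("weird label", "lovd", "other"))
  for (cs in cases)
    expect_equal(classifyLabel(cs[[1]], cs[[2]]), cs[[3]],
                 label = sprintf("%s under %s", cs[[1]], cs[[2]]))
  # whitespace-trimmed exact comparison; vectorised; always one of 4 classes
  expect_equal(classifyLabel("  Silent ", "tcga"), "silent")
  junk <- c(replicate(20, paste(sample(letters, 5), collapse = "")),
            "Missense_Mutation", "Splice_Site")
  expect_true(all(classifyLabel(junk, "tcga") %in%
                    c("missense", "truncating", "silent", "other")))
  # accepted LOVD missense set is configurable
  expect_equal(classifyLabel("AA_sub", "lovd", missenseLabels = "AA_sub"),
               "missense")
})

test_that("deduplicateUnique collapses on the (protein change, class) key", {
  rec <- rbind(
    makeRecords(2875, "Missense_Mutation", "C1", "p.N2875K"),
    makeRecords(2875, "Missense_Mutation", "C2", "p.N2875K",
                shallowDeletion = TRUE),
    makeRecords(2875, "Missense_Mutation", "C3", "p.N2875S"),
    makeRecords(100, "Nonsense_Mutation", "C4", "p.R100X"))
  cat <- classifyCatalog(rec, "tcga")
  u <- uniqueMutations(cat)
  expect_equal(nrow(u), 3L)
  # same token from different cases -> one unique; flags OR over the group
  k <- u[u$proteinChange == "p.N2875K", ]
  expect_equal(k$nCases, 2L)
  expect_true(k$shallowDeletion)
  # distinct alternate aa -> distinct unique
  expect_equal(sum(u$class == "missense"), 2L)
  # per-class unique counts sum to the number of distinct keys
  expect_equal(sum(classCounts(cat)), 3L)
})

test_that("deduplication is idempotent and falls back without tokens", {
  cfg <- syntheticConfig(nNonsilent = 120, duplicationRate = 0.3, seed = 9)
  cat1 <- classifyCatalog(generateCatalog(cfg), "tcga")
  # re-deduplicating the unique list reproduces it
  u <- uniqueMutations(cat1)
  u$caseId <- ""
  cat2 <- deduplicateUnique(u, L = proteinLength(cat1))
  cols <- c("proteinChange", "position", "class", "rawLabel",
            "shallowDeletion", "concurrentTruncating")
  expect_equal(uniqueMutations(cat2)[cols], u[cols])
  # records without a protein change key on (position, raw label)
  rec <- makeRecords(c(10, 10, 12), "Missense_Mutation",
                     c("A", "B", "C"), proteinChange = "")
  cat3 <- classifyCatalog(rec, "tcga")
  expect_equal(nrow(uniqueMutations(cat3)), 2L)
  expect_equal(catalogLog(cat3)$fallbackKeyRows, 1:3)
})

test_that("concurrent truncating calls are cross-referenced per case", {
  rec <- rbind(
    makeRecords(2875, "Missense_Mutation", "C1", "p.N2875K"),
    makeRecords(300, "Frame_Shift_Del", "C1", "p.E300fs"),
    makeRecords(2720, "Missense_Mutation", "C2", "p.D2720A"))
  cat <- classifyCatalog(rec, "tcga")
  u <- uniqueMutations(cat, "missense")
  expect_true(u$concurrentTruncating[u$proteinChange == "p.N2875K"])
  expect_false(u$concurrentTruncating[u$proteinChange == "p.D2720A"])
  # retained by the concurrent-loss filter even with the deletion flag false
  f <- filterConcurrentLoss(cat)
  expect_equal(uniqueMutations(f, "missense")$proteinChange, "p.N2875K")
  expect_equal(nrow(uniqueMutations(f, "truncating")), 1L)
})

test_that("filterConcurrentLoss subsets missense and keeps truncating", {
  rec <- rbind(
    makeRecords(c(100, 200), "Missense_Mutation", c("C1", "C2"),
                c("p.A100V", "p.A200V"), shallowDeletion = TRUE),
    makeRecords(c(300, 400), "Missense_Mutation", c("C3", "C4"),
                c("p.A300V", "p.A400V")),
    makeRecords(500, "Nonsense_Mutation", "C5", "p.R500X"))
  cat <- classifyCatalog(rec, "tcga")
  f <- filterConcurrentLoss(cat)
  expect_equal(sort(uniqueMutations(f, "missense")$position), c(100L, 200L))
  expect_equal(uniqueMutations(f, "truncating"),
               uniqueMutations(cat, "truncating"))
  expect_equal(catalogLog(f)$concurrentLossSubset, 2L)
  # all flags false -> empty missense list, still a valid catalog
  rec2 <- makeRecords(c(10, 20), "Missense_Mutation", c("C1", "C2"),
                      c("p.A10V", "p.A20V"))
  f2 <- filterConcurrentLoss(classifyCatalog(rec2, "tcga"))
  expect_equal(nrow(uniqueMutations(f2, "missense")), 0L)
  expect_true(validObject(f2))
  # neither flag columns nor case info -> uncomputable
  rec3 <- makeRecords(10, "Missense_Mutation", "", "p.A10V")
  expect_error(filterConcurrentLoss(classifyCatalog(rec3, "tcga")),
               "uncomputable")
})

test_that("catalog round-trips through writeCatalog and the run report", {
  cfg <- syntheticConfig(nNonsilent = 60, seed = 4)
  cat <- classifyCatalog(generateCatalog(cfg), "tcga")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  writeCatalog(cat, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(uniqueMutations(cat)))
  writeRunReport(cat, js)
  rep <- jsonlite::read_json(js)
  expect_equal(rep$nUnique, nrow(uniqueMutations(cat)))
  expect_equal(rep$uniqueCounts$missense,
               unname(classCounts(cat)["missense"]))
})
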