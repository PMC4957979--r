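# Synthetic stand-ins for the published mutation catalogs. These are NOT the
# real extractions: they are deterministic catalogs constructed to carry the
# same marginal composition (unique counts per class and in-domain missense
# count), so end-to-end tests can exercise the full IO -> classify -> dedup
# -> enrichment path at realistic scale without external data.

# TCGA-like: 286 unique non-synonymous mutations, 206 missense of which 42
# fall in the kinase domain (residues 2711-2962); 105 missense records carry
# a concurrent shallow-deletion flag.
makeTcgaMarginCatalog <- function() {
  posIn <- round(seq(2712, 2961, length.out = 42))
  posOut <- round(seq(10, 2700, length.out = 164))
  posMis <- c(posIn, posOut)
  posTrunc <- round(seq(30, 3040, length.out = 80))
  stopifnot(!anyDuplicated(posMis), !anyDuplicated(posTrunc))
  mis <- makeRecords(posMis, "Missense_Mutation",
                     caseId = sprintf("SYNT-%03d", seq_along(posMis)),
                     proteinChange = sprintf("p.A%dV", posMis),
                     shallowDeletion = rep(c(TRUE, FALSE), c(105, 101)))
  trunc <- makeRecords(posTrunc,
                       rep(c("Nonsense_Mutation", "Frame_Shift_Del",
                             "Splice_Site", "Frame_Shift_Ins"),
                           length.out = 80),
                       caseId = sprintf("SYNT-%03d", 206 + seq_along(posTrunc)),
                       proteinChange = sprintf("p.Q%dfs", posTrunc))
  rbind(mis, trunc)
}

# A-T-like (LOVD dialect): 447 unique point mutations, 373 truncating.
makeAtMarginCatalog <- function() {
  posTrunc <- round(seq(5, 3050, length.out = 373))
  posMis <- round(seq(12, 3020, length.out = 74))
  stopifnot(!anyDuplicated(posTrunc), !anyDuplicated(posMis))
  labTrunc <- rep(c("Nonsense_Mutation", "Frame_Shift_Del",
                    "Frame_Shift_Ins", "Splice_Site", "Stop_Codon",
                    "Large_DEL", "Start_Codon"), length.out = 373)
  trunc <- makeRecords(posTrunc, labTrunc,
                       proteinChange = sprintf("p.R%dX", posTrunc))
  mis <- makeRecords(posMis, "Missense",
                     proteinChange = sprintf("p.G%dD", posMis))
  rbind(trunc, mis)
}

writeLovdTsv <- function(records, path) {
  utils::write.table(
    data.frame(protein_change = records$proteinChange,
               effect = records$rawLabel),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
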