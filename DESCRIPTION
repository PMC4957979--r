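Package: MutHotspot
Title: Protein-Coordinate Mutation Density and Domain Enrichment for Somatic
    Mutation Catalogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hotspot analysis of somatic and germline mutation
    catalogs on protein coordinates. Reads MAF-like and LOVD-style variant
    tables, classifies variant labels into missense/truncating/silent classes,
    deduplicates to unique protein-level mutations, estimates per-residue
    mutation density with a Gaussian kernel smoother, computes fold-change
    profiles against a binomial expected-rate model with Bonferroni-corrected
    Clopper-Pearson confidence bands, and tests interval (protein-domain)
    enrichment and gene-level mutation burden by seeded permutation. Includes
    a synthetic catalog generator with a known enriched interval so every
    stage is testable without external data. Defaults target the ATM kinase
    (3057 aa including the stop codon, kinase domain at residues 2711-2962).
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'catalog-io.R'
    'density.R'
    'enrichment.R'
    'synthetic.R'
    'pipeline.R'
    'zzz.R'
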