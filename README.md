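# MutHotspot

Protein-coordinate hotspot analysis for somatic and germline mutation
catalogs, built around the ATM kinase (3057 aa including the stop codon;
kinase domain at residues 2711–2962) but parameterised for any single
protein.

Cancer sequencing projects report ATM variant calls as MAF tables;
germline A-T (ataxia-telangiectasia) catalogs arrive as LOVD-style effect
lists. The scientific questions are the same for both: after collapsing to
*unique* protein-level mutations, how do missense and truncating mutations
distribute along the polypeptide, and is the kinase domain enriched beyond
what the size of the gene predicts? MutHotspot answers them with:

* **Classification & deduplication** — raw variant labels mapped to
  missense / truncating / silent / other (TCGA and LOVD vocabularies),
  uniqueness on the (protein-change, class) key, per-case
  cross-referencing of concurrent truncating calls, quarantine of
  unparsable rows.
* **Density** — per-residue counts smoothed with a Gaussian kernel,
  `ŷ(xi) = Σj K(xi,xj) y(xj) / Σj K(xi,xj)` with
  `K(xi,xj) = exp(−(xi−xj)²/2b²)` and window `b = 80` aa; fold change
  against a uniform (or silent-calibrated) expected rate with
  Bonferroni-corrected Clopper–Pearson bands.
* **Enrichment** — seeded permutation tests: domain enrichment
  (one-sided, add-one empirical p) and gene-level burden against a cohort
  background (two-sided), plus the closed-form expectation `n·w/L`.
* **Synthetic catalogs** — a generator with a known enriched interval
  (piecewise-uniform, in/out rate ratio `f`) so every stage is testable
  without downloads.

The S4 containers (`ClassifiedCatalog`, `DensityProfile`,
`DomainEnrichmentResult`, `SyntheticConfig`) carry the run metadata —
seeds, models, label maps — so results are reproducible bit-for-bit.

## Worked example

```r
library(MutHotspot)

# a catalog at the ATM study conditions: 286 non-synonymous uniques,
# missense fraction 206/286, kinase domain enriched 2.5x
cfg <- syntheticConfig(seed = 7)
catalog <- classifyCatalog(generateCatalog(cfg), "tcga")
catalog
#> ClassifiedCatalog (tcga dialect), protein length 3057 aa
#>   429 records, 429 unique mutations
#>   unique: missense=206, truncating=80, silent=143, other=0

densityProfile(catalog, "missense")
#> DensityProfile: missense, L = 3057, b = 80 aa, n = 206 uniques
#>   expected model: uniform; alpha = 0.05, Bonferroni m = 3057
#>   max fold 1.834 at residue 2811

domainPermutationTest(catalog, "missense", nPerm = 5000, seed = 3)
#> DomainEnrichmentResult: missense in 'kinase' [2711-2962]
#>   observed 32 / expected 17.03 of n = 206 uniques (L = 3057)
#>   fold = 1.879, in/out rate ratio = 2.047, p = 0.0012 (5000 perms, seed 3)
```

The density profile says the smoothed missense frequency peaks at residue
2811 at 1.83× the uniform expectation (the dashed fold-1 line is "as
expected from gene size"). The permutation test counts 32 of the 206
unique missense mutations inside residues 2711–2962 against a uniform-null
expectation of ~17: about twice the outside rate, with an empirical
p ≈ 0.001 from 5000 seeded permutations — this particular simulated
catalog drew slightly below its generating 2.5× enrichment, which is
ordinary sampling noise at n = 206.

`runPipeline(runConfig(...))` chains the stages and writes TSV/JSON
outputs with an md5-checksummed manifest;
`inst/scripts/mutation-pipeline.R` exposes the same flow as shell
subcommands (`classify`, `density`, `enrich`, `simulate`, `run-all`).

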