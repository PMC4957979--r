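---
title: "Protein-coordinate mutation density and domain enrichment: methods"
author: "MutHotspot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein-coordinate mutation density and domain enrichment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MutHotspot)
```

# The problem

ATM is a serine/threonine kinase and tumour suppressor whose somatic
mutations recur across many cancer types. Two qualitatively different
mutation classes matter: truncating mutations (nonsense, frameshift,
splice-site), which ablate the protein, and missense substitutions, which
can leave a full-length but catalytically dead protein in place. The two
classes have different biology — a kinase-dead protein can be more harmful
than no protein — so the first analytical question for any catalog of ATM
variant calls is *where along the 3057-residue polypeptide (stop codon
included) each class concentrates*, and in particular whether missense
mutations cluster in the kinase domain (residues 2711–2962).

MutHotspot implements that analysis as a reusable, testable pipeline:

1. **catalog I/O and classification** — read MAF-like somatic tables or
   LOVD-style germline lists, map raw variant labels to
   missense/truncating/silent/other, deduplicate to unique protein-level
   mutations;
2. **density** — per-residue counts, Gaussian-kernel smoothing, an
   expected-rate null, and fold-change confidence bands;
3. **enrichment** — permutation tests for domain enrichment and gene-level
   burden;
4. **synthetic data** — a generator producing catalogs with known
   structure so every stage can be verified without external downloads.

All coordinates are 1-based and inclusive; intervals are closed.

# Classification and deduplication

Variant labels are mapped by exact token comparison after whitespace
trimming. Under the TCGA vocabulary, `Missense_Mutation`, `In_Frame_Del`
and `In_Frame_Ins` count as missense; `Nonsense_Mutation`,
`Frame_Shift_Del`, `Frame_Shift_Ins` and `Splice_Site` as truncating;
`Silent` as silent. Under the LOVD vocabulary the truncating set is
`Start_Codon`, `Frame_Shift_Del`, `Large_DEL`, `Nonsense_Mutation`,
`Frame_Shift_Ins`, `Splice_Site`, `Stop_Codon`. LOVD exports are not fully
standardised on the missense side, so the accepted missense labels are a
configurable argument (default: `Missense` plus the TCGA missense set);
every run logs its label-mapping table so the mapping in force is always
inspectable. Unknown labels never abort a run — they are routed to class
`other` and counted.

The classification always computes with these class definitions. A
reporting option (`reportClassFractions(..., grouping = "spliceStopOther")`) moves
splice-site and stop-codon labels into an "Others" group, a presentation
convention some summaries use; it never feeds the statistics.

**Uniqueness** is defined on the (protein-change token, class) pair: the
same substitution seen in many cases is one unique mutation. This matches
a protein-coordinate analysis — recurrence across cases is deliberately
collapsed, so hotspots reflect distinct variants, not sampling depth of a
common variant. Concurrent-loss flags (shallow deletion of the second
allele, or a truncating call in the same case, found by per-case
cross-referencing) are OR-ed over the carrying cases, so a unique missense
mutation is "concurrent" if any case carrying it lost the second allele.
Rows whose position cannot be parsed or lies outside `[1, L]` are
quarantined into a side report rather than dropped silently or crashing
the run; real MAF extracts are dirty and an analysis should account for
every input row.

# The density model

With `y(x)` the number of unique mutations of one class at residue `x`,
the smoothed density is the Nadaraya–Watson estimate with a Gaussian
kernel:

$$\hat y(x_i) = \frac{\sum_j K(x_i, x_j)\, y(x_j)}{\sum_j K(x_i, x_j)},
\qquad K(x_i, x_j) = \exp\!\left(-\frac{(x_i - x_j)^2}{2b^2}\right)$$

The window size `b` is 80 aa by default — wide enough to integrate over a
domain-sized neighbourhood (a ~250-aa domain spans about three windows),
narrow enough to keep the kinase-domain signal from bleeding across the
whole C-terminus. Missense and truncating mutations are smoothed
separately; silent mutations never enter a density track (they may
calibrate the expectation, below).

Numerical choices:

* The denominator is the literal kernel sum, so each $\hat y$ is a convex
  combination of the data (`min(y) ≤ ŷ ≤ max(y)`) and the protein ends
  are handled by the formula itself — no padding, reflection or
  truncation. The boundary values are simply averages over the one-sided
  neighbourhood that exists.
* The default implementation evaluates the full $L \times L$ kernel (75 MB
  of doubles at L = 3057, well within reach); an optional cutoff at
  `|Δ| > 6b` exists for longer proteins and agrees with the full sum to
  below 1e-9, since the discarded weights are ≤ exp(−18).
* The implementation is checked against a literal per-position double-sum
  oracle to 1e-12 on random inputs.

## Expected rate and fold change

The null expectation defaults to the **uniform** model: `n/L` per residue
for a class with `n` unique mutations — expectation proportional to the
size of the gene, which is also the null the permutation tests use. A
**silent-calibrated** option multiplies the smoothed silent-mutation
density by a constant non-silent:silent ratio and rescales so the
protein-wide total is `n`; it reflects the assumption that silent and
non-silent mutation rates are proportional, and lets silent mutations
stand in for local mutability. The rescaling makes the ratio's absolute
value immaterial to the fold profile — it is kept as an explicit argument
because the run descriptor records the model in its stated form. The mode
and parameters always travel with the profile.

The fold change is $\hat y(x) / \mathrm{expected}(x)$, with fold 1 the
reference. Where expected is 0 with signal present the fold is reported as
an `Inf` sentinel and the position flagged, never silently dropped.

## Confidence bands

The smoothed per-position frequency is treated as a binomial proportion
$\hat p(x) = \hat y(x)/n$ with `n` trials, and a two-sided Clopper–Pearson
interval is computed at level $1 - \alpha/m$ with Bonferroni divisor `m`
defaulting to `L` (one test per residue, α = 0.05). Bounds are divided by
the expected proportion to land on the fold scale. Clopper–Pearson was
chosen over the normal approximation because the per-position smoothed
frequencies are tiny (order 1/L) and far outside the normal regime; the
beta-quantile form generalises smoothly to the non-integer "successes"
produced by smoothing, and at $\hat p = 0$ reduces to the closed form
$1 - (\alpha'/2)^{1/n}$, which the tests assert exactly.

**A calibration caveat, stated plainly.** These bands inherit the full
binomial variance of `n` trials, while the smoothed statistic they bracket
is an average over an effective window of roughly $2b\sqrt{\pi}$ residues
and has far less variance. The bands are therefore *conservative*:
simulated per-position coverage of the true fold on uniform catalogs is
≈100%, not the nominal 95% (the package's acceptance suite measures
exactly this and the expectation is recorded there). They are honest as
conservative envelopes — a band that excludes fold 1 is strong evidence —
but they are not calibrated pointwise intervals, and narrower bands would
require an effective-sample-size argument that the binomial-with-n-trials
construction deliberately does not make.

# Permutation tests

**Domain enrichment.** The null places the `n` unique mutations of a
class independently and uniformly on `1:L`; each of `nPerm` replicates
counts how many land in the domain (default: kinase domain 2711–2962,
width 252). The p-value is the add-one upper-tail estimator
$(1 + \#\{\text{permuted} \ge \text{observed}\})/(1 + n_\text{perm})$ —
conservative and never zero. The test is one-sided because the scientific
claim is directional (enrichment). The permutation unit is the unique
mutation, not the per-case call: case identity is already collapsed by
deduplication, so there is no per-sample burden to preserve. The null is
size-based by design; mutability-weighted (signature-aware) nulls are out
of scope.

Two effect sizes are reported:

* `fold` = observed / mean permuted count — the conventional
  observed-over-expected ratio. Its denominator is the *whole-protein*
  uniform expectation `n·w/L`, so when a fraction of mutations is truly
  enriched in the domain, the estimator's expectation sits below the
  generating in/out rate ratio (at rate ratio 2.5 and the ATM geometry it
  centres near 2.2).
* `rateRatio` = (observed/w) / ((n − observed)/(L − w)) — the per-residue
  rate inside the domain relative to outside. This estimates the
  generating in/out rate ratio directly and is the quantity the recovery
  tests compare against the simulated factor; for catalogs like the ATM
  one (42 of 206 in-domain) both land near 2.5.

`closedFormExpected()` provides the analytic twin of the permutation mean
(`n·w/L`, ≈16.98 for n = 206 on the kinase domain) used to verify
convergence.

**Gene burden.** "Is the gene hyper-mutated at all?" is answered against
a caller-supplied cohort background frequency per aa (the package embeds
no cohort data): the null draws gene counts from Poisson(background ×
length) or Binomial(total cohort mutations, length share), and the
empirical p is two-sided (doubled smaller tail, add-one, capped at 1),
since a gene could be notable in either direction.

# The synthetic generator

`generateCatalog()` draws catalogs with exactly the structure the analysis
assumes: missense positions from a piecewise-uniform density with rate ∝
`f` inside the domain and ∝ 1 outside (so the in/out *rate ratio* is `f`
by construction and the in-domain probability is `f·w/(f·w + L − w)`);
truncating and silent positions uniform; labels drawn from the TCGA
vocabulary consistently with each class; synthetic protein-change tokens
distinct by construction so `n` is exact after deduplication (a
`duplicationRate` reintroduces collapsible records when dedup itself is
under test). Generation is a pure function of (config, seed).

Defaults are the study conditions of the ATM catalogs: L = 3057,
286 non-synonymous uniques with missense fraction 206/286, kinase domain
2711–2962 enriched 2.5-fold, concurrent-loss probability 105/206 among
missense. The silent:non-silent ratio is not something the mutation
catalogs pin down; 0.5 (one silent per two non-silent calls) is a
realistic exome figure and only the *shape* of the silent track matters
to anything downstream. The enrichment switch can target truncating
instead of missense for negative-control experiments.

What the generator does **not** emulate — and therefore what passing
recovery tests do not establish about real data: trinucleotide mutational
signatures and local mutability, per-tumour-type burden heterogeneity,
multi-residue in-frame events (each record contributes its start position
only), and annotation noise beyond unparsable-position rows. The
generator validates the machinery, not the biological null.

# Reproducibility and problem sizes

Every stochastic routine takes an explicit seed, restores the caller's
RNG state, and is reproducible bit-for-bit; the pipeline derives one
substream per stage from the run seed and writes md5 checksums of every
output into its manifest, so re-running a config reproduces byte-identical
files.

The shipped verification suite works at these sizes, chosen to keep each
statistical check's Monte-Carlo error well inside its decision margin:
smoother-versus-oracle on 50 random vectors (L ≤ 1000); test-size
calibration on 1000 uniform catalogs of 206 missense uniques with 2000
permutations each (the observed rejection rate sits near 4% rather than
5% — the in-domain count is discrete and the add-one estimator is
deliberately conservative, so the test's true size is slightly below
nominal); enrichment recovery on 500 catalogs at factor 2.5; permutation
mean versus closed form at 100,000 permutations; band coverage on 1000
uniform catalogs of 300 uniques (L = 500 there, since coverage depends on
the statistic, not the protein length).

# Known limitations

* The confidence bands are conservative envelopes, not calibrated
  pointwise intervals (see above).
* Uniqueness keyed on the protein-change token can differ at the margin
  from genomic-coordinate uniqueness (distinct nucleotide changes yielding
  the same protein token collapse; the same token in different classes
  does not).
* Multi-residue in-frame indels enter the density at their start position
  only.
* The uniform and silent-calibrated nulls ignore codon-level mutability;
  enrichment against those nulls is positional, not mechanistic.
* HGVS parsing extracts the first integer of the token — sufficient for
  protein-position tokens, not a general HGVS parser.
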