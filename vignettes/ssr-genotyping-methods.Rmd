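---
title: "SSR panel genotyping: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SSR panel genotyping: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrkit)
```

# The data model

A fragment-analysis SSR genotype is an *unordered* pair of allele lengths
(in nucleotides) per sample and marker. `GenotypeTable` stores the pair
canonically (`alleleA <= alleleB`) in two integer matrices, so parsing
`"246,257"` and `"257,246"` yields equal calls and equality is plain
matrix comparison. Two degenerate states are kept strictly apart:

* **missing data** (`NA` in both matrices) — the marker was not scored;
* **null alleles** (the sentinel `0`) — the marker was scored but did not
  amplify. A homozygous-null genotype `(0, 0)` is real observed data, not
  a gap: two accessions that both fail to amplify a marker *match* there
  for identity purposes, while diversity statistics must not count
  invisible gene copies.

This separation drives the estimator semantics throughout: allele
frequencies and observed heterozygosity are computed over amplifying gene
copies only, whereas clone detection treats `(0, 0)` as one more genotype
state. Parentage skips any locus where a trio member is missing *or*
null, because a silent allele could hide the transmitted copy and a
mismatch scored there would be fabricated evidence of exclusion.

A single observed peak is recorded as two identical alleles, the usual
diploid convention; true homozygotes and null-masked heterozygotes are
therefore indistinguishable in one sample, which is exactly why the
heterozygote-deficit null estimators below exist.

## Replicates: the prevailing genotype

Accessions genotyped in biological replicates share a row label.
`consolidateReplicates()` takes, per marker, the majority call among
non-missing replicate calls; disagreeing calls are reported with their
multiplicities, never silently dropped, and the consensus can only be a
call actually seen in a replicate. A tie (e.g. two replicates, two
genotypes) is broken deterministically in favor of the replicate earliest
in file order and the group is flagged `unresolved` — an auditable stand-in
for a curator's decision, chosen because any published rule for ties is
absent from the fragment-analysis tradition and randomizing would hurt
reproducibility.

# Diversity statistics

All locus statistics come from one frequency pass (`alleleFrequencies()`):

* `He = 1 − Σ p²` — Nei's gene diversity. The **biased** form is the
  default because the published marker tables this package validates
  against satisfy `Ae = 1/(1 − He)` at printed precision, which pins the
  biased estimator; the `n/(n−1)` unbiased correction is available by
  flag.
* `PIC = 1 − Σ p² − Σ_{i<j} 2 p_i² p_j²` — the Botstein form, the
  definition used by the common SSR analysis programs (the source tables
  name PIC without printing a formula).
* `Ae = 1/Σ p²`, identical to `1/(1 − He)` by construction.
* `PI = Σ p⁴ + Σ_{i<j} (2 p_i p_j)²` — the probability that two
  unrelated Hardy–Weinberg individuals share the locus genotype. The test
  suite checks this against brute-force enumeration of all genotype pairs
  to 1e-12; the panel value is `PI_t = Π PI_i`, which assumes linkage
  equilibrium between markers — the reason the panel designer enforces a
  minimum physical distance between same-chromosome markers.
* Shannon's index uses the natural log (the convention of the named
  analysis software).
* Allelic richness is hypergeometric rarefaction to `g` gene copies
  (default: all copies at the marker), the standard way to compare allele
  counts at unequal sample sizes.
* The null-allele rate defaults to Chakraborty's
  `r = (He − Ho)/(He + Ho)`; Brookfield's `(He − Ho)/(1 + He)` is a flag
  away. Both may legitimately go negative under heterozygote excess, and
  the published collection indeed reports a slightly negative lower end.
  The exact estimator behind the published appendix values is not
  recoverable, so these two standard forms are offered and only their
  directional behavior (positive under injected nulls) is asserted.

## Reconstructing spectra from printed summaries

`He` and `PIC` are two independent functions of the frequency moments
`S2 = Σ p²` and `S4 = Σ p⁴` (`He = 1 − S2`,
`PIC = 1 − S2 − S2² + S4`), and `PI = 2 S2² − S4`. Hence a printed
`(k, He, PIC)` row determines `PI` exactly even though the frequencies
themselves were never published. `frequenciesFromSummary()` finds a
k-allele spectrum matching the two moments by simplex-parameterized
least squares (softmax coordinates, BFGS from several deterministic
starts, Nelder–Mead polish, relative moment residuals). Because
statistics printed to three decimals can be *marginally infeasible* —
there may be no exact simplex point with both moments — residuals up to
2e-3 (relative) are accepted and the nearest feasible spectrum returned,
which perturbs the derived `PI` by at most the same order. This is how
the acceptance script recomputes the published panel's `PI_t` from its
printed per-marker table.

# Identity and parentage

Clone/synonym detection counts **allele-level** mismatches: per locus,
`2 − |multiset intersection|` of the two pairs, skipping loci missing on
either side (pairs with fewer than half their loci comparable are flagged
low-confidence). The allele metric, rather than a locus metric, matches
how near-identical varieties are described in practice ("differing by one
or two alleles"). Clusters are single linkage; at threshold 0 they are
exact equivalence classes and `deduplicate()` keeps the first member of
each in input order. Near matches (1–2 alleles) are *reported, not
merged* — distinguishing a mutation-carrying clone from a sibling is
curatorial judgment, not arithmetic.

Parent-pair search applies the zero trio-mismatch criterion with selfing
permitted (`parent_a == parent_b`), the offspring itself excluded. The
search prunes candidates that fail to supply either offspring allele at a
locus where all candidates are complete (such a candidate can never
qualify), then verifies every surviving unordered pair exhaustively —
pruning affects speed only, never the result. LOD ranking is the
error-free Marshall-type ratio: per locus,
`log10(T / H)` with `T` the fraction of the four equiprobable gamete
combinations reproducing the offspring genotype and `H` its
Hardy–Weinberg probability. No genotyping-error model is layered on
because the headline zero-mismatch counts do not depend on it. When
clone clusters are supplied, pairs identical up to clone membership are
counted once.

A consequence worth knowing: with a fully typed polymorphic panel, a
*parent* can be "resolved" by a pair of its own offspring (the trio read
backwards is also Mendelian-consistent). The collection-level summary
reports what the criterion yields; interpreting direction is up to the
analyst.

# Multiplex panel design

A single-reaction panel places each marker in a (dye × size-window) slot;
the shipped defaults are four dyes by four windows (100–150, 200–250,
300–350, 400–450 nt). Constraints: one marker per slot, at most two
markers per chromosome, same-chromosome pairs at least 1 Mbp apart
(linkage hygiene for the `PI_t` product), and the expected amplicon range
inside its window shrunk by a 5 nt guard margin. Candidate screening
(`filterCandidates()`) is a pure conjunction of the published rules:
≤ 2 mapping failures, ≥ 3 alleles, repeat tract ≤ 60 nt (stutter
control), no allele above frequency 0.5, and motif-dependent minimum
sequence-based PIC (0.8 / 0.7 / 0.6 for 2 / 3 / ≥4 nt units). Whether the
60 nt cap refers to the reference tract or the longest allele is
ambiguous in its source; the filter applies it to the stored
`repeat_length_nt` field.

The validator treats *range overlap within a dye* as the hard failure —
that is what actually breaks allele calling — while a range spilling past
its nominal window is a warning, because published windows are
approximate and several published marker ranges do exceed them by
10–14 nt. Assignment is greedy by quality with the tightest feasible
window preferred; instance sizes are tiny, and fixed pre-assignments
(proven legacy markers) are honored first. Legacy markers without
published coordinates are simply skipped by the distance rule rather than
guessed.

# The synthetic-data generator

`simulateFrequencies()` (Dirichlet spectra on a motif-length lattice,
optional PIC targeting by rejection), `simulatePopulation()` (two
independent allele draws per genotype — the exact sampling model under
which the PI formula holds), `simulateCross()` (uniform gamete choice,
optional single-step mutation, default rate 0),
`simulateFounderPopulation()` (repeated crossing inside a small founder
pool) and `injectArtifacts()` (hidden null alleles, allele typos, planted
clones with a truth log) generate every input the pipeline consumes. All
are seeded through R's integer-state generator and fully reproducible.

`simulateStudyCollection()` composes them into a stand-in for a genotyped
germplasm collection at the published study's scale: per-marker spectra
reconstructed from the published 16-marker summary table, 294 unique
genotypes of which 123 are recorded pedigree offspring of crosses between
collection members, and 21 synonym rows for 315 samples in total. Those
counts are the stated conditions of the collection it emulates, not free
parameters.

What the generator does **not** emulate: electropherograms and stutter
(genotypes are the unit of analysis), population structure and admixture
within the founder set (founders are i.i.d. Hardy–Weinberg), linkage
between markers, and realistic pedigree depth (study-collection offspring
are first-generation crosses). Tests passing on these data therefore
demonstrate algorithmic correctness under the stated model — Mendelian
completeness, planted-truth recovery, estimator consistency — not
robustness to structured real-world germplasm.

# Numerical and scale choices

* Problem sizes: the study-scale collection is 315 × 16; pairwise scans
  are vectorized per locus over all sample pairs, and the parentage scan
  over all 294 × ~43k candidate pairs runs in about a second thanks to
  the single-parent feasibility prune.
* Simulation sizes in the checks: Hardy–Weinberg recovery at
  n ∈ {100, 1000, 10000}; the top-marker PIC recomputation uses n = 5000,
  where the bootstrap standard error of PIC is well under the 0.005
  band it is compared at; Mendelian completeness uses 1000 trios.
* Ties in UPGMA joins are broken by `stats::hclust`'s deterministic
  ordering; Mantel permutations (default 999, one-sided "greater") are
  seeded, so `p` can never fall below `1/(1 + n_perm)`.
* The genetic distance is allele-sharing (`1 − shared/(2 · loci)`),
  chosen because the distance behind the published dendrograms is not
  recoverable from its description; distance-dependent published figures
  (e.g. a tanglegram Mantel r) are consequently not comparison targets
  anywhere in the package, and only internal-consistency properties are
  asserted for the clustering layer.

# Known limitations

* Statistics printed to three decimals propagate: reconstructed `PI_t`
  values inherit a percent-level uncertainty, and identities such as
  `Ae = 1/(1 − He)` can deviate by `0.0005/(1 − He)²` at high
  heterozygosity purely from print rounding.
* The null-allele and allelic-richness estimator choices are assumptions
  (flagged above); only directional properties are guaranteed.
* The LOD model has no genotyping-error term, so a single typo excludes a
  true parent — by design, matching the strict zero-mismatch criterion.
* `PI_t` assumes linkage equilibrium; the 1 Mbp spacing rule reduces but
  does not prove independence.
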