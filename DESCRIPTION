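Package: ssrkit
Title: Multiplex SSR Genotyping, Diversity Statistics, and Parentage Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microsatellite (SSR) fingerprinting of clonally
    propagated crops scored by fragment analysis. Provides S4 containers for
    marker panels and diploid multilocus genotype tables with explicit
    null-allele and missing-data semantics, replicate consolidation to the
    prevailing genotype, per-locus and panel-level diversity statistics
    (observed and expected heterozygosity, polymorphic information content,
    effective allele number, Shannon index, rarefied allelic richness,
    null-allele estimates, and the probability of identity of two unrelated
    individuals), clone and synonym detection, exhaustive Mendelian
    parent-pair search under a zero trio-mismatch criterion with LOD ranking,
    selection of candidate SSRs and design of single-reaction multiplex
    panels under dye, size-window and linkage constraints, allele-sharing
    distances with UPGMA dendrograms and Mantel comparisons, and a seeded
    synthetic-data generator for Hardy-Weinberg populations, pedigrees,
    founder bottlenecks and genotyping artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, ape, vegan
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
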