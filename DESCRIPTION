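Package: shelterload
Title: Sheltered Genetic Load Linked to Self-Incompatibility Alleles
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the recessive deleterious load sheltered by
    dominant versus recessive alleles at the sporophytic self-incompatibility
    (SSI) locus of Brassicaceae. Provides a forward-time Wright-Fisher
    simulator of a panmictic population under SSI with a pollen dominance
    hierarchy and a fully linked locus accumulating recessive deleterious
    mutations; trio-based phasing of S-linked haplotypes; a sliding-window
    likelihood scan contrasting haplotype topologies grouped by S-allele
    versus by population; codon degeneracy classification (0-fold/4-fold);
    per-lineage fixed and segregating mutation counts with Poisson dominance
    regressions; Hudson-type FST profiles; and permutation tests for
    Mendelian segregation distortion and homozygote phenotype contrasts.
    Synthetic data generators with machine-readable truth exercise the whole
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    methods,
    data.table,
    jsonlite,
    Rcpp,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    BiocGenerics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse,
    withr
Config/testthat/edition: 3
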