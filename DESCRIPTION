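Package: invintro
Title: Chromosomal Inversion Discovery, Long-Read Breakpoint Validation,
    and Introgression Analysis for Colony Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing chromosomal inversions and
    introgression in diploid resequencing panels such as mosquito colony
    cohorts. Merges per-sample structural-variant candidate calls by
    reciprocal overlap, validates inversion breakpoints by competitive
    alignment of long reads against reference and inverted junction
    sequences calibrated on a repeat-matched artificial-breakpoint null,
    and classifies reassembled supercontig junctions. Computes windowed
    nucleotide diversity, Weir-Cockerham F_st, runs of homozygosity,
    ancestry-informative markers, Patterson's D with block-jackknife
    significance, and Martin's fD introgression scans with peak calling,
    and builds maximum-parsimony SNP phylogenies with bootstrap support
    for inversion regions. Includes a fully seeded synthetic-data
    generator (drifted subspecies panels, spiked inversions, long reads,
    caller-like candidate sets) with exported ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    phangorn,
    vcfR,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
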