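Package: camsnp
Title: Polyploid-Aware SNP Discovery, Array Genotyping, Linkage Mapping
    and Diversity Analysis for Hexaploid Oilseeds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven pipeline for single-nucleotide polymorphism
    marker development in an undifferentiated hexaploid genome. Generates a
    synthetic three-subgenome genome with known allelic and homeologous
    variation, emulates EcoRI reduced-representation paired-end sequencing,
    maps reads with a unique-seed rule, calls variants under configurable
    depth/variant-fraction profiles, and applies polyploid-specific
    post-discovery filters (zero-variance parental alleles, 100-bp clean
    flanks, a designability surrogate, synteny spread selection) to assemble
    a GoldenGate-style assay panel. Downstream stages call two-channel array
    genotypes from polar intensities with cluster-pattern quality control,
    build a recombinant-inbred-line linkage map (two-point LOD grouping,
    seriation, Kosambi distances, segregation-distortion audit), and compute
    population-genetic summaries: per-locus diversity and polymorphism
    information content, Weir-Cockerham F-statistics, AMOVA, allele-sharing
    neighbour-joining trees with locus bootstrap, maximum-likelihood
    admixture with Evanno delta-K model choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    ape,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
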