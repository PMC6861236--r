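Package: polyscan
Title: Ploidy-Aware Divergence Scans, Haplotype Phasing and Topology
    Weighting for Mixed-Ploidy Population Genomics
Version: 0.1.0
Authors@R:
    person("polyscan", "developers", email = "polyscan@example.org",
           role = c("aut", "cre"))
Description: Windowed population-genomic analysis of species pairs in which
    diploid and autotetraploid populations coexist. Reads mixed-ploidy VCF
    genotypes (diploid 0/1 and tetraploid 0/1/1/1 calls) into an allele-dosage
    matrix, computes per-window divergence statistics (allele frequency
    difference, dXY, Hudson-type Fst, the ploidy-independent Rho intraclass
    correlation, and fixed differences), calls empirical outlier windows and
    tests outlier-set overlap between independent scans by permutation,
    phases diploid and tetraploid genotypes within windows by an iterative
    linkage-disequilibrium maximisation heuristic, infers per-window
    genealogies with BIONJ, and quantifies genealogical discordance by exact
    or Monte-Carlo topology weighting over the fifteen rooted five-taxon
    topologies, classifying them into species, introgression and incomplete
    lineage sorting classes. A structured-coalescent simulator with
    whole-genome duplication events, localized bidirectional introgression
    and imposed selective sweeps provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    VariantAnnotation,
    rtracklayer,
    GenomicRanges,
    SummarizedExperiment,
    S4Vectors,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
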