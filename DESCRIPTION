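Package: strainmark
Title: Strain-Specific Marker Discovery and Absolute qPCR Quantification
    from Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for detecting and quantifying individual
    bacterial strains. Gene families are clustered across a collection of
    annotated genomes into a pangenome presence/absence matrix, partitioned
    into core, soft-core, shell, cloud and strain-unique compartments, and
    candidate strain-unique genes are re-screened at the nucleotide level
    with a seeded local-alignment engine against all non-target genomes and
    optional external sequence databases. Surviving markers feed a qPCR
    primer designer with nearest-neighbor melting-temperature thermodynamics
    and in-silico PCR specificity certification. Core-genome bi-allelic SNP
    distances and neighbor-joining phylogenies summarise collection
    diversity, and a qPCR module fits standard curves, computes
    amplification efficiencies and converts Ct values to absolute abundances
    (CFU per gram). A synthetic-collection generator with full ground truth
    supports validation of every stage without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
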