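Package: spacerdiv
Title: CRISPR Spacer Array Diversity and Independent Acquisition in
    Microbial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of CRISPR-encoded viral-resistance diversity against
    housekeeping-gene (MLSA) diversity in a single microbial population.
    Extracts ordered spacer arrays from repeat-delimited locus sequences,
    defines spacer identity by an ungapped 88%-identity/17-nt-overlap match
    rule with single-linkage clustering, aligns arrays at the spacer level to
    detect spacer-loss events and ancestral groups, classifies non-ancestral
    fuzzy spacer matches as independent acquisitions, assigns MLSA alleles and
    genotypes, and estimates diversity by OTU binning, individual-based
    rarefaction and Chao1 richness. Includes a forward simulator of a
    hot-spring population (leader-end spacer acquisition from a shared
    PAM-constrained virus pool, spacer loss, locus loss, MLSA mutation and
    gene conversion) emitting FASTA inputs plus ground-truth event logs so
    every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    mclust,
    vegan,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
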