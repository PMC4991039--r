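Package: ptcmap
Title: Parent-Specific Genetic Linkage Maps from Pseudo-Testcross SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction of parent-specific genetic linkage maps for an
    outbred F1 family using the pseudo-testcross strategy. Provides the full
    analysis chain from dual-reference VCF genotype calls to ordered maps:
    alignment- and genotype-level quality filters (edit distance, alignment
    score, MQ, DP, GQ), Mendelian 1:1 segregation chi-square tests and
    missingness filters, cross-validation of SNP loci called against two
    parental rough reference assemblies by genotype-vector identity (Hamming
    distance zero), marker binning, two-point recombination fraction and LOD
    estimation with linkage-phase inference, LOD-threshold linkage grouping,
    marker ordering by minimum sum of adjacent recombination fractions with an
    exact brute-force oracle, and Kosambi map distances. Includes an F1
    meiosis simulator producing dual "reference view" VCF datasets with known
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
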