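Package: fggtest
Title: Functional Gene Group Association Testing for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("fggtest", "maintainers", email = "fggtest@example.org",
           role = c("aut", "cre"))
Description: Self-contained gene-set association testing for quantitative
    traits in genome-wide association data. Per-SNP additive linear
    regression p-values are aggregated over all SNPs annotated to a group
    of functionally related genes as a sum of -log10(p), and significance
    is assessed by permutation of phenotypes over genotypes, which leaves
    the linkage-disequilibrium structure of the genotype matrix intact.
    Includes SNP-to-gene annotation with asymmetric upstream/downstream
    windows, genomic-control lambda estimation and correction, within-site
    trait standardization, pairwise-r2 LD tagging and array coverage
    accounting, non-central chi-square power calculations for quantitative
    trait loci, and a synthetic-data generator producing LD-blocked
    genotypes with planted group-distributed effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
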