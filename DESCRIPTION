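Package: germDiv
Title: Germplasm Diversity Analysis and Core Collection Construction for
    Allotetraploid SNP Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing SNP-array genotypes of allotetraploid crop
    germplasm collections. Implements marker quality control with recoding of
    subgenome-collapsed heterozygote calls, supervised market-type assignment
    by discriminant analysis of principal components (DAPC) calibrated on
    phenotype-congruent reference accessions, admixture-model ancestry
    inference by Gibbs sampling with multi-run stability selection of the
    number of clusters, distance-based diversity analytics (allele-sharing and
    Modified Rogers distances, Ward trees, expected heterozygosity), and
    core-collection construction by average entry-to-nearest-entry distance
    optimisation around breeder-nominated entries. Ships a synthetic
    collection generator so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
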