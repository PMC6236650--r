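Package: expansionOrigin
Title: Geographic Origin Inference for Population Expansions from
    Georeferenced Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatially explicit inference of the geographic source of a
    population expansion from georeferenced multilocus genotypes such as
    microsatellite-typed crop landraces. Local genetic diversity (Nei's
    unbiased gene diversity, averaged across loci) is measured in
    fixed-radius kernels over a latitude/longitude grid; every grid node is
    then scored as a candidate origin by the Pearson correlation between
    great-circle distance to the accepted kernels and kernel diversity,
    under the serial-founder expectation that diversity declines with
    distance from the origin. Two candidate origin sites are compared by a
    permutation test that reassigns genotype vectors over sampling
    locations. A serial-founder expansion simulator with stepwise
    microsatellite mutation makes every stage of the pipeline testable, and
    companion summaries cover genotype PCA, the Evanno delta-K statistic
    for external Bayesian clustering logs, and granule-bound starch
    synthase I (GBSSI) waxy-phenotype tabulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    pracma,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'sample-table.R'
    'io.R'
    'spatial.R'
    'diversity.R'
    'origin.R'
    'simulate.R'
    'summaries.R'
    'gbssi.R'
    'plots.R'
    'sites.R'
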