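Package: strdiv
Title: STR Diversity, DLA Haplotype and Pedigree Analysis for Bottlenecked Dog Breeds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the genetic consequences of breeding
    bottlenecks in closed dog-breed populations. Computes per-locus and
    population-mean microsatellite (STR) diversity statistics (Na, Ne, Ho,
    He, FIS), internal relatedness (raw and adjusted against an outbred
    reference population), codominant genotypic distance and principal
    coordinate analysis, expectation-maximization phasing of dog leukocyte
    antigen (DLA) class I and II STR haplotype blocks with registry naming,
    case/control haplotype relative-risk association statistics, and
    pedigree algorithmics (generation-capped inbreeding coefficients,
    founder-set ancestry, influential-ancestor ranking and ancestry-disease
    curves). A seeded simulation module generates bottlenecked pedigrees,
    gene-dropped STR genotypes, linked DLA haplotype blocks and
    liability-threshold disease phenotypes for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
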