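Package: peroxitools
Title: Multi-Level Analysis of Peroxisomal Protein Targeting and Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for the computational assays used in systematic
    studies of the peroxisomal proteome in budding yeast. Computes hydrogen-bond
    occupancy statistics from molecular-dynamics distance series and classifies
    candidate PTS1 cargo peptides against a known-cargo stability envelope; fits
    one-site binding-saturation models to fluorescence-anisotropy titrations;
    normalizes flow-injection metabolomics ion-intensity matrices (outlier
    removal, LOWESS injection-order drift correction, linear OD600 correction),
    builds z-scored mutant metabolome profiles, clusters them by Ward linkage on
    Manhattan distances and attaches per-cluster GO enrichment; and tests lipid
    class enrichment of significantly changing lipids. Every input can be
    simulated with designed ground truth, so the full pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
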