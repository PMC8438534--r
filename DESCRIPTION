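Package: phosphoscreen
Title: Image-Based Screening of Rice Genotypes for Low-Phosphorus Tolerance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening crop genotypes for tolerance to phosphorus
    deficiency from shoot images and replicated trait tables. Segments plants
    from RGB photographs by hue-saturation-brightness thresholding and derives
    top-view canopy geometry (projected area, convex hull, calliper length,
    minimum enclosing circle, moment-ellipse eccentricity) and leaf inclination
    angles; computes phosphorus utilisation efficiency and dry-matter
    contribution percentages; evaluates seven stress tolerance and
    susceptibility indices (MPI, MRP, REI, TOL, STI, SSI, DTE) with their
    selection patterns; and runs the multivariate screening battery: balanced
    two-way analysis of variance with sum-of-squares partition, broad-sense
    heritability from variance components, Pearson correlation, principal
    component analysis with mean-threshold genotype selection, and Ward
    clustering with row Z-score scaling. Includes synthetic generators for
    plant-like images with exact known geometry and for trait tables with known
    variance structure, so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    grDevices,
    igraph,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
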