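Package: blastomorph
Title: Surface-Domain Morphometrics and YAP Localisation in Cleavage-Stage Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of blastomere geometry and YAP nuclear
    localisation in preimplantation embryos. From co-registered 3D cell and
    nucleus label volumes the package extracts per-cell surface meshes,
    partitions each cell's limiting membrane into exposed (apical), junctional
    and contact (basolateral) domains by surface proximity, computes a panel of
    shape and position descriptors (volume, surface area, sphericity,
    oblateness, prolateness, domain-area proportions, apical-to-junction
    ratio), and measures nuclear-to-cytoplasmic YAP and apical-to-basolateral
    pERM intensity ratios. A k-means threshold separates high from low nuclear
    YAP cells, and Ward hierarchical clustering with an adaptive tree cut
    assigns inside-like / outside-like / undefined states; Spearman correlation
    matrices and normality-gated group tests complete the statistics layer. A
    synthetic embryo generator with spherical, cylindrical (microchannel) and
    planar (slab) confinement envelopes provides ground-truth data for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    cluster,
    ggplot2,
    knitr,
    mclust,
    optparse,
    patchwork,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
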