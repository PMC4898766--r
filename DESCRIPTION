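Package: betagrad
Title: Community Diversity and Ecotone Structure Along Elevation Gradients
Version: 0.1.0
Authors@R: person("Betagrad", "Maintainers", email = "maintainers@betagrad.org",
    role = c("aut", "cre"))
Description: Tools for incidence-based community analysis of georeferenced
    specimen surveys along short elevation gradients: building species-by-unit
    incidence matrices from specimen tables, nonparametric species-richness
    estimation (Chao2 with CV-based bias-correction switching, ICE, first- and
    second-order jackknife, sample-based rarefaction and extrapolation),
    Sorensen and Jaccard compositional similarity with reconstruction of
    integer shared-species counts from published summaries, beta-diversity
    partitioning into turnover and nestedness (Baselga) or replacement and
    richness-difference (Carvalho) components, UPGMA clustering of
    communities, distance decay of similarity, sliding-window detection of
    ecotone boundaries over elevation bins, and agreement scoring between
    competing species delimitations (agree/split/merge). Includes a seeded
    generator of synthetic gradient communities with known ground truth for
    parameter-recovery testing, modelled on a leaf-beetle survey of the
    Nui Chua National Park (Vietnam).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
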