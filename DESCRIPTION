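Package: wrenlink
Title: Linking Insectivorous Bird Diet, Arthropod Availability and Nesting Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking nestling diet characterized by COI
    metabarcoding, habitat-element-resolved arthropod availability, and nesting
    performance for an insectivorous bird of coastal sage scrub. Provides a
    similarity-threshold taxonomy cascade with lowest-common-ancestor tie
    resolution, diet frequency-of-occurrence and relative-read-abundance
    metrics, length-to-biomass allometric conversion, cell-level biomass
    aggregation and marginal means, Bray-Curtis/PERMANOVA/PCA community
    statistics, cover-weighted territory upscaling of prey availability, and
    territory-level correlations of availability with first egg date and
    fledgling counts. Includes a synthetic-study generator that emulates the
    full field design (territories, habitat elements, strata, time blocks)
    with known ground truth so every stage is testable end to end.
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
    vegan,
    lme4,
    emmeans
Config/testthat/edition: 3
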