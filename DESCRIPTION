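Package: visitnet
Title: Visit-Based Interaction Strength in Plant-Pollinator Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative plant-pollinator networks from survey
    records under two measures of interaction strength: the conventional
    encounter-based measure (abundance-weighted encounter frequency) and a
    visit-based measure that multiplies encounter strength by the mean
    number of flowers visited per encounter. Computes species-level
    descriptors (species strength, push-pull interaction asymmetry, d'
    specialization) and network-level descriptors (weighted NODF
    nestedness, H2' specialization, interaction evenness, plant and
    pollinator generality), and provides the statistical machinery to
    compare the two measures: descriptor-on-descriptor regressions with
    slope-versus-one tests, ratio-of-change regressions against floral
    display, and bootstrap subsampling of encounter events with paired
    t-tests. Includes a synthetic survey generator emulating the sampling
    design of a Mediterranean scrubland pollination study, so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
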