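Package: windsift
Title: Low-Impact Wind Siting on Disturbed Lands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for identifying low-impact areas for wind
    energy development on already-disturbed lands. Builds a binary human
    disturbance footprint from land cover, impervious surface, topographic
    change, well-field kernel density, rasterized linear infrastructure and
    buffered settlements; subtracts jurisdiction-specific wildlife exclusions
    expressed as declarative rule sets; applies a patch-size/isolation filter;
    converts surviving area into installable wind capacity (GW) by wind power
    class; and audits turbine locations against the result. Includes a seeded
    synthetic-landscape generator so every stage is testable without external
    data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'features.R'
    'grid.R'
    'disturbance.R'
    'exclusions.R'
    'suitability.R'
    'patches.R'
    'capacity.R'
    'turbines.R'
    'synth.R'
    'io.R'
    'pipeline.R'
    'tables.R'
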