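Package: supercoilr
Title: Chromosome Supercoil Density from Site-Specific Recombination Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of bacterial chromosome supercoiling measured
    with gamma-delta resolvase "supercoil sensor" assays. Fits and inverts the
    monotone calibration curve relating diffusible supercoil density (sigma_D)
    to resolution efficiency; turns replicate colony counts into efficiencies,
    censored detection-limit values, mutant impact factors and per-genotype
    genome-wide aggregates; estimates transcription elongation rates from
    beta-galactosidase induction time courses by hinge (changepoint)
    regression; and provides a deterministic twin-domain kinetic simulator of
    diffusible supercoil density on a circular, domain-partitioned chromosome
    under transcription flux, gyrase, topoisomerase I and topoisomerase IV.
    Includes seeded synthetic-data generators for every input the pipelines
    consume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
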