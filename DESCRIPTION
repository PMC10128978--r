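Package: msipcr
Title: Microsatellite Instability Calling from Non-Labeled Capillary Electrophoresis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microsatellite instability (MSI) analysis of paired
    tumor/normal capillary-electrophoresis electropherograms on a
    five-marker mononucleotide panel (BAT-25, BAT-26, NR-21, NR-24, NR-27).
    Provides peak detection and two-anchor (15/1000 bp) log-linear size
    calibration with alignment-marker quality control, the >= 3 bp
    major-band shift / new-minor-band instability rule with Bethesda
    MSI-H/MSI-L/MSS classification, a two-tier screening-to-high-resolution
    gel workflow, limit-of-detection estimation from tumor-fraction dilution
    series, MSI-PCR vs mismatch-repair immunohistochemistry concordance
    reporting, and a fully seeded electropherogram simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
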