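Package: psichart
Title: Automated Chart Checks for LDR Prostate Brachytherapy Documentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A schema-driven verification engine for prostate seed implant
    (PSI) chart documentation. Extracts typed fields from Word (DOCX) and
    text-layer PDF chart documents, applies three layers of rule-based
    checks (data completeness, cross-document consistency, allowable value
    range) including an institutional seed-ordering nomogram with a +/-5
    seed tolerance, runs monthly documentation audits, and renders
    variance-highlighting summary reports. Ships a synthetic-chart
    generator with controlled defect injection for validating the rule
    engine against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
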