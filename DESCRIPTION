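Package: glycoquant
Title: Bottom-Up Polysaccharide Quantitation from LC-MS/MS
    Oligosaccharide Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computational pipeline for bottom-up glycomic quantitation of
    food polysaccharides. Oligosaccharide peaks from LC-MS/MS runs of
    chemically depolymerized polysaccharides are annotated with
    monosaccharide compositions by exhaustive combinatorial matching,
    assigned to parent polysaccharides through a composition plus
    retention-time fingerprint library, and quantified both relatively
    (peak-area fractions) and absolutely (top-3 averaged, zero-intercept
    external calibration) with method detection limit, bias and CV
    statistics. Includes a seeded synthetic LC-MS run generator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mzR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
biocViews: MassSpectrometry, Metabolomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
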