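Package: rmzero
Title: Chromatographic Lipophilicity from Reversed-Phase TLC Retention Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating compound lipophilicity from reversed-phase
    thin-layer chromatography (RP-TLC) plate measurements. Retention factors
    are transformed to R_M values, extrapolated linearly to zero organic
    modifier to obtain the R_M0 lipophilicity index, and converted to absolute
    logP (logP_TLC) through a calibration line fitted on standards with known
    literature logP. The package also quantifies concordance between
    experimental and algorithm-calculated logP columns (correlations, spread
    and range summaries), clusters compounds and prediction methods by
    single-linkage agglomeration on Euclidean distances, screens molecular
    descriptors against the Lipinski, Ghose, Veber and Egan drug-likeness
    rules, and ships a synthetic plate generator with known ground truth for
    end-to-end validation.
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
    ape,
    withr
Config/testthat/edition: 3
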