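Package: scarscreen
Title: Temporal Expression Screening of Scarless Wound Healing Versus Skin Fibrosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A cross-dataset temporal expression screen for nominating
    fibrosis-driver candidate genes. Classifies genes as transiently induced
    in a scarless (oral mucosa) wound-healing time course, classifies genes
    as persistently upregulated in a bleomycin-type skin-fibrosis course,
    and intersects the two screens; genes with the amphiregulin (Areg)
    pattern -- a sharp early induction that resolves by day 3 in scarless
    healing but persists throughout fibrogenesis -- are the candidates.
    Includes comparative-Ct (delta-delta-Ct) relative quantification for
    qPCR validation, a synthetic time-course generator with planted
    temporal classes for end-to-end testing, and stable tab-separated
    input/output formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
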