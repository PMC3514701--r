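Package: homeovert
Title: Homeotic Vertebral Transformations, Severity Scoring and
    Malformation Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying homeotic transformations of the human
    vertebral column in perinatal autopsy cohorts. Classifies per-vertebra
    rib morphology into eight vertebral pattern classes defined by shifts
    of the cervico-thoracic, thoraco-lumbar and lumbo-sacral boundaries,
    scores each pattern on an ordinal 0-9 severity scale, codes autopsy
    findings into primary organ-system malformation flags with germ-layer
    and morphogenetic-process derivations, and tests severity-malformation
    associations with simple correspondence analysis and logit-link
    binomial generalized linear models fitted by iteratively reweighted
    least squares. A seeded synthetic cohort generator with the study's
    statistical structure makes the whole pipeline testable without
    access to the original autopsy archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
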