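Package: dicescore
Title: Diverse Convergent Evidence Scoring for Candidate Disease Risk Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores structured evidence dossiers for candidate disease risk
    factors under the Diverse Convergent Evidence (DiCE) rubric. Evidence from
    omic screens (with standard or alternative statistical validation),
    biological databases or literature, and laboratory experiments is combined
    into a composite score that classifies the support for a (factor,
    phenotype) pair as strong or weak. Includes fixed-effect inverse-variance
    meta-analysis from odds ratios with confidence intervals,
    significance-threshold classification, batch scoring of GWAS hit tables,
    offline literature-search providers for semi-automated evidence gathering,
    canonical worked-example dossiers, and a seeded synthetic dossier
    generator.
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
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
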