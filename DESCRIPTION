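Package: gesturenet
Title: Gestural Repertoire Overlap and Social Bonding Networks in Primates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how overlap (homogeneity) and non-overlap
    (heterogeneity) in primate gestural repertoires relate to dyadic social
    bonding. Builds per-individual gesture repertoires from focal-follow
    event records, scores dyadic repertoire agreement with Cohen's kappa,
    converts instantaneous scan samples into dyadic bonding rates (minutes
    per hour co-present in a party), assembles weighted social networks with
    normalized degree centrality, and tests dyadic and node-level hypotheses
    with quadratic-assignment permutation methods (MRQAP with double
    semi-partialling) and binomial random-intercept mixed models. Includes a
    synthetic focal-follow data generator with a tunable coupling between
    repertoire overlap and proximity, so the full pipeline can be exercised
    and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
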