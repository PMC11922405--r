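Package: painpro
Title: Multidimensional Patient-Reported Pain Outcomes After Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the multidimensional analysis of acute postoperative
    pain in registry data from total knee arthroplasty. Computes composite
    patient-reported outcome scores on the numeric rating scale (pain
    composite score, physical and emotional interference, adverse events,
    and a global PRO-Score), converts postoperative opioid administrations
    to oral morphine equivalents via a versioned conversion table, and fits
    covariate-adjusted models for group comparisons across anesthesia
    techniques: a beta regression for the bounded pain composite score with
    estimated marginal means and Tukey-adjusted pairwise contrasts, and a
    logistic model for opioid use with g-computation percentage-point
    treatment contrasts. A synthetic registry generator with known ground
    truth supports validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmmTMB
Config/testthat/edition: 3
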