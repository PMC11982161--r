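Package: dyadcrqa
Title: Categorical Cross-Recurrence Analysis of Dyadic Speech Turn-Taking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify speech coordination in dyadic conversation from
    binary speech/silence time series. Reads Praat TextGrid or interval CSV
    annotations and bins them at 1 Hz, builds categorical cross-recurrence
    plots under complementary (speaker/listener) matching, and computes global
    and line-of-synchrony recurrence rates, diagonal cross-recurrence profiles
    with the absolute leader-follower quotient, and anisotropic line measures
    (directional laminarity and trapping time with their absolute relative
    differences). Includes shuffled-surrogate pseudosynchrony baselines, a
    coupled two-state turn-taking simulator for whole studies with personality
    covariates and appraisal items, and the dyad-level statistical stage
    (random-intercept mixed models, standardized betas, ICC, and
    Benjamini-Hochberg correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
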