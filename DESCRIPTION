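Package: dyadisc
Title: Dyadic Neural Similarity and Default-Prior Bayes Factor Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dyadic social-interaction studies that pair
    naturalistic-fMRI inter-subject correlation (ISC) with behavioral outcomes.
    Computes per-dyad region-wise and whole-brain neural similarity from
    parcel-level BOLD timecourses (with trimming, concatenation, motion-similarity
    and run-exclusion handling), scores cooperative-game communicative success and
    perceived interaction quality, and ranks predictor models with a from-scratch
    Jeffreys-Zellner-Siow default-prior Bayes factor regression engine supporting
    all-possible-subset comparison, interaction tests, relative Bayes factors,
    evidence bands, prior-sensitivity sweeps and exploratory region-wise mapping.
    Includes a synthetic dyad-data generator (imaging plus behavior) so the whole
    pipeline is testable end to end without access-restricted human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
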