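Package: dyadrank
Title: Dominance Assessment from Dyadic Competition Tests in Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying established social hierarchies in pairs of
    cage-mate rodents from timestamped ethogram event logs of home-cage
    competition tests (modified food competition, sucrose and water
    competition, tube test). Computes trial-aligned behavioral summaries,
    dominance indices, conflict and conflict-resolution indices,
    dominant/submissive classification with a noise band, peak-conflict epoch
    detection, cross-test reliability, and a weight-controlled regression
    linking food-competition rank to tube-test outcomes. Includes exact
    small-sample nonparametric tests and a synthetic dyad-cohort generator
    with exported ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
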