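Package: dmat
Title: Scoring and Analysis of Observational Dampness and Mold Assessments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recording, validating, scoring and analysing
    observational (visual and olfactory) assessments of dampness and
    mold-related damage in buildings. Implements the semi-quantitative
    0-3 scoring of four dampness/mold factors (mold odor, water
    damage/stains, visible mold, wet/damp materials) across eight room
    components, room-level summary scores and color-band classification,
    building- and campaign-level aggregation, exposure indices for
    epidemiologic use (time-weighted average room scores and a mixed
    microbial exposure index built from agent-specific decile ranks),
    inter-observer concordance, longitudinal change detection between
    repeat assessments, and seeded generators of synthetic assessment
    campaigns. CSV input/output follows the flat spreadsheet layout used
    in the field, including its blank-means-zero conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
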