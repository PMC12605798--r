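Package: tnfiswitch
Title: TNF Inhibitor Switching Trajectories and Note-Based Reason Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds tumor necrosis factor inhibitor (TNFi) treatment
    trajectories from longitudinal medication-order tables, normalizes
    free-text drug names to canonical generic and biosimilar categories,
    detects switches between consecutive encounters, and evaluates
    structured extraction of switch events and switching reasons from
    clinical notes. Provides a zero-shot prompt registry with a fixed JSON
    output schema, deterministic reference and noisy extractor backends,
    silver-standard labels derived from medication orders, micro-F1 under
    two null-label policies, pairwise win/loss/tie rates, concordance
    statistics, Sankey-style flow tables, and a seeded synthetic-EHR
    generator with planted ground truth for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
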