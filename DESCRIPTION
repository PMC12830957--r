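Package: gazesum
Title: Scene Understanding Maps and Task-Dependent Fixation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing free-viewing eye movements against
    scene-understanding maps (SUMs). A SUM scores each object in a scene
    by how much its removal changes observers' scene descriptions, using
    rating tables or embedding similarity, and renders the scores as
    box-anchored Gaussians. The package builds smoothed fixation heat
    maps with people-region exclusion, correlates maps across viewing
    tasks and across Winograd scene pairs, evaluates prediction maps
    with the shuffled-AUC statistic, counts fixations on object
    categories and cumulative-difference curves, classifies description
    correctness from embedding similarity, and provides hierarchical
    bootstrap inference with Benjamini-Hochberg/Yekutieli false
    discovery rate control. A synthetic-data generator emulates the
    structure of a four-condition (free viewing, scene description,
    object search, counting) eye-tracking study so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
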