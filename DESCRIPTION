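Package: dcida
Title: Nudging Layer for Patient Decision Aids via Multi-Criteria Decision Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating 'nudged' patient decision aids
    driven by a weighted additive multi-criteria decision analysis (MCDA)
    model. Implements constant-sum ("budget pie") preference elicitation with
    slider-linked proportional redistribution, 5-point option ratings mapped to
    0-100 scores, weighted-additive option totals with a pre-selected default
    option, and a summary layout whose rows are ordered by weight rank, sized
    in proportion to weights and shaded by score. Includes a usability
    analytics battery (I-DT fixation detection, area-of-interest assignment,
    relative fixation duration, heatmap grids, System Usability Scale and
    Decisional Conflict Scale uncertainty-subscale scoring), a parametric
    agent simulation of four decision biases (unstable values, order effects,
    overweighting of rare events via prospect-theory probability weighting,
    and information overload with default adherence), and synthetic-data
    generators for decision problems, participant responses and gaze logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
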