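Package: sprbench
Title: Benchmarking Human and Automated Surgical Phase Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking surgical phase recognition (SPR) in
    robot-assisted partial nephrectomy and laparoscopic cholecystectomy
    workflows. Implements the constrained temporal sampling strategy used to
    build single-frame and video-snippet survey questions from phase-annotated
    procedures, the evaluation metrics used to score raters and frame-level
    predictors (accuracy, support-weighted F1, and a normalized L-half
    confusion-spread statistic), the paired Wilcoxon signed-rank comparison of
    question modalities with Bonferroni correction, and Spearman rank
    correlations against confidence and perceived difficulty. A synthetic-data
    layer simulates procedure timelines from published per-phase duration
    tables, survey respondents of three expertise groups, and frame-level
    predictors with temporal smoothing, so the full benchmark runs end-to-end
    with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
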