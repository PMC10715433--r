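Package: recallorder
Title: Scoring and Analysis of Free-Recall Retrieval-Practice Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing idea-unit-coded free-recall data from
    text-learning experiments that compare retrieval-practice tasks
    (whole-text recall, section recall) with restudy across groups
    (e.g. ADHD vs. typically developed students). Provides the quantity
    measure (proportion of idea units recalled) and a recall-order score
    (mean absolute displacement between each recalled unit's output
    position and its rank among recalled units, divided by the number
    recalled), generation of the fully counterbalanced 36-version design,
    split-plot mixed-design ANOVA with Bonferroni-adjusted pairwise
    comparisons and effect sizes, ASRS screening utilities, and a
    synthetic-data simulator so the whole pipeline can be exercised and
    validated without access to raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
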