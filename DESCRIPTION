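Package: hiddensingle
Title: Strategy Learning Dynamics on Hidden-Single Sudoku Puzzles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying rapid human strategy acquisition on the
    "hidden single" Sudoku technique: a procedural generator for
    hidden-single puzzles with a controlled digit-role structure
    (target, distractor, in-house, absent), balanced Latin-square
    transfer designs, a four-strategy Markov model of aggregate strategy
    dynamics with maximum-likelihood fitting, exact monotone-path
    hidden Markov model posteriors for individual participants, a
    mixed-effects solver classifier for practice-phase learning curves,
    transfer-effect regressions for test-phase accuracy and response
    times, and a synthetic-cohort simulator so the full pipeline can be
    exercised without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
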