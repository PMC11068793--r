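Package: periodx
Title: Rule-Based Periodontal Diagnosis, Diagnostic-Accuracy Scoring and
    Wilcoxon Power Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic rule engine for diagnosing periodontal and
    peri-implant conditions from full-mouth periodontal charts under the
    2017 AAP/EFP classification (case definition, staging, grading,
    extent, gingival and peri-implant status, and six secondary-condition
    categories), together with a serializable question-tree front end that
    is provably equivalent to the engine, a seeded synthetic-cohort
    generator built by rule inversion, diagnostic-accuracy tables for
    paired control/test study designs, an exact Wilcoxon matched-pairs
    signed-rank test, and Monte-Carlo power simulation for paired
    non-parametric designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
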