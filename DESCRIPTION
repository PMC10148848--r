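Package: patchforage
Title: Sequential Patch Depletion Foraging: Simulation, Optimality, and
    Delay-Discounting Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the sequential patch depletion operant procedure used
    to study foraging choice and delay discounting in rats. Provides a
    Marginal Value Theorem solver for the task's geometric reward schedule,
    a discrete-event simulator of single sessions and full 24-session
    protocols for parameterised agents, extraction of the five dependent
    measures (patch changes, time in patch, rejection volume, water rate,
    deviation from optimality), anchored hyperbolic discounting fits with
    normalized area under the curve, and cohort-level statistics (composite
    scores, Pearson matrices, Meng's z for dependent overlapping
    correlations, mixed ANOVA with partial eta squared, Bonferroni
    post-hocs), together with a synthetic-cohort generator for parameter
    recovery and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
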