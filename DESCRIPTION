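Package: propulsr
Title: Propulsion Metrics and Symmetry from Split-Belt Treadmill Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts per-step propulsion peak and impulse from the
    anteroposterior ground reaction force recorded on an instrumented
    split-belt treadmill, estimates stance phases from foot-marker
    trajectories, computes paretic/non-paretic propulsion symmetry, and fits
    linear mixed models of gait speed on propulsion outcomes for hemiparetic
    and control cohorts. Includes a synthetic gait-data generator with
    ground-truth records for parameter-recovery validation of the full
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    pbkrtest,
    signal,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
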