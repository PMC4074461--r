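Package: swayboard
Title: Balance-Board Posturography and Measurement Reliability
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for clinical posturography with four-load-cell balance
    boards. Reconstructs center-of-pressure (COP) trajectories from corner
    load-cell forces, preprocesses them (uniform resampling, Butterworth
    low-pass filtering), computes the standard sway metrics (COP path length
    and average velocity), and quantifies measurement reliability and
    agreement: two-way ANOVA intraclass correlation coefficients with 95%
    confidence intervals, standard error of measurement, paired-difference
    tests, and Bland-Altman limits of agreement. An Ornstein-Uhlenbeck sway
    simulator and a variance-components study generator provide synthetic
    multi-session reliability studies with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
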