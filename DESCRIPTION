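Package: maizecast
Title: Process-Based Simulation and Regression Forecasting of Off-Season Maize Yield
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Daily-timestep maize growth simulation built on a thermal-time
    development index, softmax carbon partitioning, allometric canopy and
    height relations and a layered soil-water bucket, runnable at potential
    and water-limited production levels.  From the simulated seasons and the
    driving weather the package derives 10-day forecasting-window indicators
    (dry masses, leaf area index, crop height, soil water, temperature,
    rainfall and diffuse radiation), aggregates them across climate zones by
    cultivated area, and fits per-window yield forecasting models by
    bidirectional stepwise regression with variance-inflation and
    Durbin-Watson screening, leave-one-out cross-validation and a
    goodness-of-fit suite (R2, Willmott's d, Nash-Sutcliffe efficiency,
    SDEP).  A synthetic multi-zone study generator with known ground truth
    makes the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), lmtest, car, withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
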