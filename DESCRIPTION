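Package: pbrgrowth
Title: Batch Growth Kinetics and Aeration Response for Lab-Scale Photobioreactors
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing batch microalgal growth campaigns in
    bubble-column photobioreactors run under atmospheric CO2. Provides
    optical-density to biomass calibration with evaporation/top-up volume
    correction, six primary growth models (logistic, logistic with lag,
    modified Gompertz, Baranyi-Roberts, a hybrid linear-logistic two-phase
    model, and a Monod-by-Gauss aeration-temperature rate surface),
    nonlinear least-squares fitting with R2/RMSE model comparison, a
    change-point procedure for the linear-to-logistic transition time, an
    aeration-temperature surface analysis, and a seeded synthetic-campaign
    generator so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
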