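Package: dmfgain
Title: Gain-Modulated Dynamic Mean-Field Modeling of Cortical BOLD Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysically based modeling of large-scale cortical dynamics and
    their pharmacological modulation. Implements a dynamic mean-field network of
    coupled excitatory-inhibitory populations on a structural connectome, with
    per-node feedback inhibition control, receptor-expression-weighted neural
    gain modulation, Balloon-Windkessel hemodynamics, and semi-analytic BOLD
    covariance via linearization and the Lyapunov equation. Provides global
    brain connectivity (GBC) statistics with analytic global signal regression,
    grid-search calibration of global coupling and gain parameters at group and
    subject level, variogram-matched spatial-autocorrelation-preserving
    surrogate map null tests, principal component and subspace analyses of map
    ensembles, experiential regression maps, and a synthetic-data generator for
    connectomes, expression maps, and subject cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
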