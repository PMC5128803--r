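Package: torsim
Title: Variability-Aware In Silico Cardiac Safety Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Single-cell human endocardial and Purkinje action-potential
    simulation under multichannel drug block, with inter-individual
    variability in intracellular spermine (via inward-rectifier I_K1
    rectification) and L-type calcium conductance. Provides
    conductance-block pharmacology (Hill-type IC50 scaling), steady
    pacing, spermine-step and variability-grid protocols, per-beat
    action-potential biomarkers with early-afterdepolarization
    detection, a pD2-threshold decision tree with simulation-based
    torsadogenic risk grouping, and an extreme-value (3^n) population
    risk scan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
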