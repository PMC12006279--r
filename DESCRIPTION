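Package: pwvbp
Title: Pulse-Wave-Velocity-Based Blood Pressure Prediction with a 1D
    Arterial Testbed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cuffless blood-pressure estimation from pulse wave
    velocity (PWV). Implements the conventional single-PWV model based on
    the Bramwell-Hill equation and a two-PWV model that accounts for the
    time-varying wave speed of a nonlinearly stiffening artery, together
    with the supporting estimation chain: intersecting-tangents foot
    detection, foot-to-foot transit-time PWV, theoretical PWV(t) from
    pressure and area waveforms, and a linear PWV-area scaling. A
    deterministic testbed generates ground-truth two-station pressure,
    area and flow waveforms by solving the 1D mass and momentum equations
    for a compliant vessel with a nonlinear tube law and a three-element
    Windkessel outlet, so both prediction models can be exercised and
    compared at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
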