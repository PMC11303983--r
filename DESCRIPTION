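Package: symtip
Title: Response Symmetry of Tipping Points in a Mutual-Inhibition
    Microbial Ecosystem Model
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a symmetric two-functional-group microbial ecosystem
    (cyanobacteria and sulfur-reducing bacteria) in which each group produces
    a substrate (oxygen or sulfide) that inhibits the other group, while both
    compete for phosphorus.  The system exhibits alternative oxic and anoxic
    stable states, hysteresis, and tipping points along counter-varying
    oxygen and sulfide diffusivity gradients.  Provides the stepwise
    stable-state ("temporal approach") protocol with periodic immigration
    rescue, detection and quantification of tipping-point locations and shift
    magnitudes, response-symmetry reports, and scans over system asymmetry
    (the oxygen half-inhibition constant of the sulfur reducers) and
    environmental asymmetry (the log-width of the sulfide diffusivity range).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
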