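Package: bioreactr
Title: Programmable Bioreactor Control with a Simulated Culture Twin
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Script-driven control of a low-cost perfusion bioreactor for
    adherent cell culture: a nine-command protocol language (Loop, Vol, Goto,
    Wait, Dir, Ch, Stir, Start, Msgbox) with a validating interpreter, device
    models for a stepper-motor syringe pump, a multi-channel selector and
    per-well stirrers, non-contact colorimetric pH sensing of phenol-red media
    via a linear green-intensity calibration, and a deterministic digital twin
    of the culture wells (logistic growth, metabolic acidification, linear
    buffering) so that automated media-refresh protocols and pH-maintenance
    behaviour can be executed and verified entirely in simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
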