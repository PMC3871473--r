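Package: cardiopower
Title: Beat-by-Beat Cardiac Power Integral and Stroke Work Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying left-ventricular energy transfer to the
    aorta on a beat-by-beat basis. Computes the cardiac power curve (the
    instantaneous product of aortic pressure and aortic flow), its per-cycle
    time integral, and pressure-volume loop stroke work from synchronized
    1 kHz hemodynamic recordings, including conductance-catheter alpha
    calibration against a transit-time flow probe. Provides the agreement
    analysis between the two energy measures: per-animal through-origin
    regression and correlation, Bland-Altman summaries, and a no-intercept
    random-slope mixed model with animal as random effect and intervention
    as fixed effect. Ships a time-varying elastance plus three-element
    Windkessel simulator that emulates a porcine preparation under baseline,
    reduced preload, increased afterload, dobutamine, nitroprusside and
    metoprolol conditions, so the full pipeline is testable without animal
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
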