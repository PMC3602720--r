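Package: smid
Title: Semi-Markov Illness-Death Models with Piecewise-Constant Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a three-state illness-death model (healthy, illness, death,
    no recovery) with piecewise-constant Gompertz-type transition intensities
    on the age time scale, where the illness-to-death intensity depends on the
    sojourn time spent in the illness state (a semi-Markov model).
    Interval-censored illness onsets are integrated out of the likelihood by
    composite Simpson quadrature; left-censored onsets (illness before study
    entry) are handled by an EM-inspired imputation of the onset age.
    Includes a piecewise-exponential trajectory simulator emulating a
    longitudinal panel design with left truncation, stratified studentised
    bootstrap confidence intervals with Box-Cox variance stabilisation, and
    microsimulation-based graphical goodness of fit (Kaplan-Meier and
    prevalence envelopes).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
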