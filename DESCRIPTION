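Package: chromdoe
Title: Design-of-Experiments and Monte Carlo Defect-Rate Optimization for
    Liquid Chromatography Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quality-by-design development of liquid chromatography
    assays: Plackett-Burman screening and Box-Behnken response-surface designs
    in coded units, ordinary-least-squares response-surface models with
    standardized-effect (Pareto) analysis, Derringer desirability profiling,
    Monte Carlo defect-rate estimation under random factor variation with
    specification limits, Latin-hypercube simulation experiments with a
    Gaussian-process surrogate and jackknife diagnostics for defect-rate
    minimization, a synthetic chromatogram generator built from exponentially
    modified Gaussian peaks, system-suitability metrics (USP tailing,
    theoretical plates, resolution, signal-to-noise), in vitro release
    kinetics (zero order, first order, Higuchi, Korsmeyer-Peppas) with
    mechanism classification, and quantification utilities (calibration
    curves, encapsulation efficiency, molar extinction coefficients by the
    chromatographic and spectrophotometric routes).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr
Config/testthat/edition: 3
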