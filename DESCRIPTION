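Package: aukcalls
Title: Vocal Repertoire and Contextual Valence Analysis of Little Auk Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of the vocal repertoire of the
    little auk (Alle alle), a colonial Arctic seabird. Provides a synthetic
    harmonic call generator parameterised by published per-call-type acoustic
    statistics, Praat-style acoustic parameter extraction (autocorrelation
    fundamental-frequency tracking, spectral energy quartiles and centre of
    gravity, amplitude- and frequency-modulation rates), call-type
    discrimination via principal component analysis and linear discriminant
    analysis with leave-one-out cross-validation and a permutation null, and
    linear models quantifying the effect of assigned contextual valence on
    call acoustics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
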