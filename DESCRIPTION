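Package: rhythmshift
Title: Age-Dependent Rhythmic Alteration of Diurnal Gene-Expression Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies age-dependent reshaping of diurnal gene-expression
    rhythms. Detects daily-cycling genes by fixed-period cosinor regression,
    parameterizes single-cycle waveforms by full width at half maximum (FWHM)
    with circular wraparound, identifies single-oscillation genes and tests
    FWHM change between ages by replicate-permutation resampling, and maps
    expression profiles onto the 24-hour circle with a ridge-regression
    physiological-time estimator. Includes a synthetic diurnal time-course
    generator with known ground-truth waveform parameters so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
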