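Package: firecycles
Title: Detection of Weekly Cycles in Daily Vegetation-Fire Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and characterise day-of-week cycles in daily
    counts of vegetation fires. Provides spectral identification of hidden
    periodicities in log-transformed count series (periodogram, Fisher's
    g-test and sequential Whittle testing), harmonic regression with
    autoregressive AR(7) errors fitted by empirical-Bayes conjugate
    inference, simultaneous highest-posterior-density credible bands for
    the mean function, and Monte-Carlo band-membership and exceedance
    probabilities comparing each weekday against Sunday. Includes readers
    for MCD14ML-style active-fire records and ESRI ASCII anthrome rasters,
    anthrome labelling and daily aggregation, and a synthetic-data
    generator that reproduces the statistical structure of the global
    daily fire-count series for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
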