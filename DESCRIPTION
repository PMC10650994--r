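Package: leafcgsd
Title: Color Gradation Skewness-Distribution Analysis of Canopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts the 20 color gradation skewness-distribution (CGSD)
    parameters (mean, median, mode, skewness and kurtosis of the red, green,
    blue and gray-level pixel-intensity distributions) from background-removed
    canopy RGB images, tests the gradation arrays for normality (Lilliefors
    with Monte-Carlo p-values, Jarque-Bera), relates the parameters to five
    hourly meteorological factors (air temperature, relative humidity,
    atmospheric pressure, dew-point temperature, vapor pressure) by Pearson
    correlation screening and partial-F stepwise least-squares regression in
    both directions (leaf-color response models and meteorological inversion
    models), scores holdout predictions with a relative-error accuracy
    statistic with outlier flagging, and splits samples into temperature
    regimes by exact one-dimensional 2-means clustering. A synthetic-study
    module generates physically consistent hourly weather series and canopy
    images with planted linear weather-to-color maps so the whole pipeline is
    testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
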