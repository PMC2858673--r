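Package: stereopop
Title: Population Coding and Template-Matching Decoding of 2D Binocular Disparity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a population of binocular energy-model neurons with Gabor
    receptive fields, tuned to a range of orientations, spatial frequencies,
    phase disparities and horizontal disparities, but all tuned to zero
    vertical disparity. Each unit reports the effective binocular correlation
    of a random-dot stereogram within its receptive fields, converted to
    Poisson spike counts. A template-matching decoder correlates the
    population's single-trial response against stored mean responses for a
    grid of candidate two-dimensional disparities, recovering both the
    horizontal and the vertical disparity of the stimulus even though no
    encoding neuron is tuned to non-zero vertical disparity. Includes
    stereogram generation (correlated and anticorrelated), receptive-field
    construction, tuning-surface measurement, template banks, decoding
    experiments with per-component error statistics, and figure rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
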