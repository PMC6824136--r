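Package: isotrack
Title: Dual-Tracer Winter Foraging Inference from Geolocators and Stable
    Isotopes
Version: 0.1.0
Authors@R:
    person("Isotrack", "Developers", email = "isotrack@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring winter foraging locations and trophic
    position of marine predators by combining light-level geolocator
    tracks with stable isotope measurements of inert tissue (feathers).
    Provides geolocator fix filtering and kernel-density utilisation
    surfaces, dual-isotope (delta-13C / delta-15N) reference isoscapes
    with ordinary kriging and lipid normalisation, Monte-Carlo
    calibration-offset estimation between consumer tissue and a
    reference isoscape, Bayesian per-cell geographic assignment with
    likely-region extraction and between-year overlap statistics,
    trophic-position comparison statistics (exact Mann-Whitney,
    Yates-corrected chi-squared, predator-prey isotopic spacing, CPUE
    gridding on ICES statistical rectangles), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
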