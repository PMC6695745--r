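Package: accelcal
Title: Age-Equivalent Accelerometer Calibration with Net Oxygen Consumption as Criterion
Version: 0.1.0
Authors@R:
    person("accelcal", "maintainers", email = "accelcal@example.org", role = c("aut", "cre"))
Description: Tools for calibrating raw triaxial accelerometry against energy
    expenditure and for classifying free-living physical activity. Converts raw
    acceleration to a band-pass filtered intensity metric in milli-g (and ENMO
    for comparison), computes criterion measures from oxygen-consumption traces
    (resting and standing VO2, net VO2, MET, Froude-type equivalent speed),
    fits anchored smoothing splines per age group to derive accelerometer
    cut-points for light through very vigorous activity at hip and thigh
    placements, and aggregates free-living epoch series into per-day and
    per-group time-in-intensity summaries with non-wear, night-window and
    valid-day rules. Includes a seeded synthetic-data generator for treadmill
    calibration sessions and free-living weeks with closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
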