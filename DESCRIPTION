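Package: xylotomo
Title: Xylogenesis Phenology from X-Ray CT Gray-Value Profiles of Wood Microcores
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures maturing and mature xylem widths on high-resolution X-ray
    computed tomography scans of wood microcores by penalized-spline smoothing of
    radial cell-wall gray-value profiles and plateau detection on the derivative
    confidence band. From seasonal series of such widths it estimates the
    secondary-growth calendar (5%/95% critical dates, durations, mean daily rates)
    with monotone shape-constrained splines, derives intra-seasonal biomass
    production dynamics from summed xylem gray values, and benchmarks paired
    measurement methods with major-axis (model II) regression and case-based
    bootstrap tests. Includes a synthetic-data generator with known ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    splines,
    utils,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
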