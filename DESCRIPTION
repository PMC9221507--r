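Package: leafmorph
Title: Leaf Shape Morphometrics from Boundary Coordinates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures leaf size and shape from closed boundary polygons of
    the lamina edge: area, length, width profile, maximum width and its
    axial position, and bilateral split areas.  Computes six leaf-shape
    indices (width-to-length ratio, ellipticalness index, proximal and
    distal log width-ratio indices, bilateral log area-ratio, centroid
    ratio) and leaf dry mass per unit area.  Fits the Montgomery
    proportionality between leaf area and the length-width product, the
    free-slope power law of area versus length, and the fixed-slope-2
    similarity model, with correlation, RMSE and confidence intervals.
    Provides superellipse shape theory (gamma-function area coefficient
    and the ellipticalness-index curve), a seeded synthetic generator of
    site-tree-leaf populations with known ground truth for parameter
    recovery, and a random-intercept mixed-model stage with the
    intraclass correlation coefficient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
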