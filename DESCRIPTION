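Package: gva
Title: Geometric Viability Assay: Colony-Forming Units from Colony
    Positions in Conical Gels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates colony-forming-unit (CFU) concentrations from the
    axial positions of colonies embedded in a conical gel volume (the
    geometric viability assay). Colonies seeded uniformly in a cone fall
    along the axis with density 3x^2/h^3, so the positions of the first
    few colonies from the tip encode the total concentration. The package
    provides the order-statistics estimator, an inhomogeneous-Poisson
    colony simulator, Monte-Carlo robustness analyses (missed colonies,
    tip-position error, replicate noise), a printable-ruler generator for
    arbitrary cone geometries, a synthetic tip-image renderer with
    matching segmentation and multi-scale colony detection, and a
    consumables calculator, together with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'estimator.R'
    'simulator.R'
    'robustness.R'
    'ruler.R'
    'imaging-render.R'
    'imaging-segment.R'
    'io.R'
    'consumables.R'
    'gva-package.R'
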