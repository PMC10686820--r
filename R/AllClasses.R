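#' @include AllGenerics.R
NULL

.SHAPES <- c("circular_cone", "square_pyramid", "cylinder", "wedge")

#' Conical embedding-vessel geometry
#'
#' Describes the vessel the sample is embedded in: the axial length `h`
#' of the cone (mm), the gel volume `V` (microlitres; 1 uL = 1 mm^3) and
#' the shape class. Length and volume are independent fields: a real
#' pipette tip is not a mathematically exact cone, and the axial density
#' depends only on `h` while the concentration arithmetic uses only `V`.
#'
#' `circular_cone` and `square_pyramid` share the same axial density
#' (cross-section scales as \eqn{x^2} in both); `cylinder` and `wedge`
#' are provided for comparing dynamic range across vessel shapes.
#'
#' @slot shape One of `"circular_cone"`, `"square_pyramid"`,
#'   `"cylinder"`, `"wedge"`.
#' @slot axialLength Axial length h in mm.
#' @slot volume Gel volume V in uL.
#'
#' @param shape,axialLength,volume See slots.
#' @return `ConeGeometry()` returns a validated `ConeGeometry` object.
#' @seealso [geometryProfile()] for the built-in p200 profile,
#'   [axialPdf()], [axialCdf()], [axialQuantile()].
#' @examples
#' g <- ConeGeometry("circular_cone", axialLength = 36, volume = 150)
#' axialCdf(g, 18)
#' @aliases axialLength gelVolume
#' @export ConeGeometry
#' @exportClass ConeGeometry
setClass("ConeGeometry",
  slots = c(shape = "character", axialLength = "numeric",
            volume = "numeric"))

ConeGeometry <- function(shape = "circular_cone", axialLength, volume) {
  new("ConeGeometry", shape = shape, axialLength = as.numeric(axialLength),
      volume = as.numeric(volume))
}

setValidity("ConeGeometry", function(object) {
  msg <- character()
  if (length(object@shape) != 1L || !object@shape %in% .SHAPES)
    msg <- c(msg, sprintf("shape must be one of: %s",
                          paste(.SHAPES, collapse = ", ")))
  if (length(object@axialLength) != 1L || !is.finite(object@axialLength) ||
      object@axialLength <= 0)
    msg <- c(msg, "axialLength must be a single positive number (mm)")
  if (length(object@volume) != 1L || !is.finite(object@volume) ||
      object@volume <= 0)
    msg <- c(msg, "volume must be a single positive number (uL)")
  if (length(msg)) msg else TRUE
})

#' One tip's colony observations
#'
#' Container for a single embedded tip: the sorted axial positions of its
#' colonies (mm from the apex), the vessel geometry, the sample-to-gel
#' dilution factor and the counted gel volume. Optional radial
#' coordinates (`y`, `z` in mm, relative to the axis) may be carried for
#' rendering; the estimator ignores them by construction.
#'
#' @slot tipId Character identifier.
#' @slot positions Numeric vector, sorted ascending, within `[0, h]`.
#' @slot radial Numeric matrix with columns `y_mm`, `z_mm` (zero rows if
#'   absent); same row order as `positions`.
#' @slot geometry A [ConeGeometry-class].
#' @slot dilutionFactor Sample concentration / in-gel concentration
#'   (>= 1; the standard embedding gives 100).
#' @slot gelVolume Gel volume actually counted, uL.
#'
#' @param positions,geometry,tipId,dilutionFactor,gelVolume,radial See slots.
#'   Unsorted positions are sorted with a warning; `gelVolume` defaults to
#'   the geometry's volume.
#' @param object A `ColonySet`.
#' @return `ColonySet()` returns a validated `ColonySet`.
#' @aliases positions nColonies dilutionFactor geometry
#' @examples
#' cs <- ColonySet(c(9, 18, 27), geometryProfile("p200"))
#' nColonies(cs)
#' @export ColonySet
#' @exportClass ColonySet
ColonySet <- function(positions, geometry, tipId = "tip1",
                      dilutionFactor = 100, gelVolume = NULL,
                      radial = NULL) {
  positions <- as.numeric(positions)
  if (is.unsorted(positions)) {
    warning("colony positions were not sorted; sorting ascending")
    ord <- order(positions)
    positions <- positions[ord]
    if (!is.null(radial)) radial <- radial[ord, , drop = FALSE]
  }
  if (is.null(radial))
    radial <- matrix(numeric(0), 0, 2,
                     dimnames = list(NULL, c("y_mm", "z_mm")))
  radial <- as.matrix(radial)
  colnames(radial) <- c("y_mm", "z_mm")
  if (is.null(gelVolume)) gelVolume <- geometry@volume
  new("ColonySet", tipId = as.character(tipId), positions = positions,
      radial = radial, geometry = geometry,
      dilutionFactor = as.numeric(dilutionFactor),
      gelVolume = as.numeric(gelVolume))
}

setClass("ColonySet",
  slots = c(tipId = "character", positions = "numeric", radial = "matrix",
            geometry = "ConeGeometry", dilutionFactor = "numeric",
            gelVolume = "numeric"))

setValidity("ColonySet", function(object) {
  msg <- character()
  h <- object@geometry@axialLength
  p <- object@positions
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > h)))
    msg <- c(msg, sprintf("all positions must lie in [0, %g] mm", h))
  if (is.unsorted(p))
    msg <- c(msg, "positions must be sorted ascending")
  if (nrow(object@radial) && nrow(object@radial) != length(p))
    msg <- c(msg, "radial must have one row per colony (or zero rows)")
  if (object@dilutionFactor < 1)
    msg <- c(msg, "dilutionFactor must be >= 1")
  if (object@gelVolume <= 0)
    msg <- c(msg, "gelVolume must be positive (uL)")
  if (length(msg)) msg else TRUE
})

#' Result of a CFU estimation
#'
#' Output of [estimateCfu()]: the concentration estimate on the original
#' sample scale and the in-gel scale, the counted axial interval and
#' colony count, a below-limit-of-detection flag (zero colonies), and the
#' running estimate as colonies are added ([convergenceTrace()]).
#'
#' @slot cfuPerMlSample Estimate for the original sample (CFU/mL); `NA`
#'   when below the limit of detection.
#' @slot cfuPerMlGel In-gel concentration estimate (CFU/mL).
#' @slot nCounted Colonies inside the counted interval (the numerator).
#' @slot interval `c(x1, x2)` in mm.
#' @slot belowLod Logical.
#' @slot lod Limit of detection (sample scale) carried as an upper bound
#'   when `belowLod`.
#' @slot k Colonies requested; `mode` the counting convention used.
#' @slot mode Character.
#' @slot trace data.frame with columns `k`, `estimate` (sample scale).
#' @param object A `CfuEstimate`.
#' @aliases cfuPerMl isBelowLod
#' @export
#' @exportClass CfuEstimate
setClass("CfuEstimate",
  slots = c(cfuPerMlSample = "numeric", cfuPerMlGel = "numeric",
            nCounted = "integer", interval = "numeric",
            belowLod = "logical", lod = "numeric", k = "numeric",
            mode = "character", trace = "data.frame"))

#' Perturbation description for robustness experiments
#'
#' How to corrupt a counted colony set before re-estimating: remove
#' `nMissing` colonies under a removal policy, and/or displace the
#' assumed apex by `tipOffset` mm (positive = apex assumed farther from
#' the colonies, all axial positions increase).
#'
#' @slot nMissing Non-negative integer.
#' @slot removalPolicy `"uniform_random"`, `"nearest_tip_first"` or
#'   `"farthest_first"`.
#' @slot tipOffset Signed offset in mm.
#' @param nMissing,removalPolicy,tipOffset See slots.
#' @return A validated `PerturbationSpec`.
#' @export PerturbationSpec
#' @exportClass PerturbationSpec
PerturbationSpec <- setClass("PerturbationSpec",
  slots = c(nMissing = "integer", removalPolicy = "character",
            tipOffset = "numeric"),
  prototype = list(nMissing = 0L, removalPolicy = "uniform_random",
                   tipOffset = 0))

setValidity("PerturbationSpec", function(object) {
  msg <- character()
  if (object@nMissing < 0) msg <- c(msg, "nMissing must be >= 0")
  if (!object@removalPolicy %in%
      c("uniform_random", "nearest_tip_first", "farthest_first"))
    msg <- c(msg, "unknown removalPolicy")
  if (length(msg)) msg else TRUE
})

#' Optical configuration of a tip camera
#'
#' Physical pixel size at the object plane, additive noise level,
#' background intensity and the maximum random tilt applied when
#' rendering. Built-in profiles: `"canon"` (6.6 um pixels) and
#' `"iphone12"` (13.7 um), the two rigs whose resolution limits bound
#' the assay's dynamic range.
#'
#' @slot pixelSize Pixel size, um.
#' @slot noiseSd Gaussian intensity noise s.d. (intensity units, image
#'   scaled 0..1).
#' @slot background Background intensity level.
#' @slot rotationJitter Maximum random tilt, degrees.
#' @param pixelSize,noiseSd,background,rotationJitter See slots.
#' @seealso [opticsProfile()]
#' @export OpticsProfile
#' @exportClass OpticsProfile
OpticsProfile <- setClass("OpticsProfile",
  slots = c(pixelSize = "numeric", noiseSd = "numeric",
            background = "numeric", rotationJitter = "numeric"),
  prototype = list(pixelSize = 6.6, noiseSd = 0, background = 0.95,
                   rotationJitter = 0))

setValidity("OpticsProfile", function(object) {
  msg <- character()
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0 um")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Rendered synthetic tip image with ground truth
#'
#' A rasterised greyscale image of one agarose-filled tip plus the
#' ground truth it was rendered from, kept as a sidecar for round-trip
#' testing: colony axial positions, rendered centre pixels and radii,
#' the true apex pixel and axis tilt.
#'
#' @slot pixels Numeric matrix (rows x cols), intensities in `[0, 1]`.
#' @slot optics An [OpticsProfile-class].
#' @slot geometry The [ConeGeometry-class] rendered.
#' @slot truth data.frame: `x_mm`, `row_px`, `col_px`, `r_px` per colony.
#' @slot apex True apex `c(row, col)` in pixel coordinates.
#' @slot axisAngle True tilt from vertical, degrees.
#' @slot baseRadius Rendered base radius, mm.
#' @slot resolutionWarning TRUE when some colony was rendered with
#'   radius < 2 px (the colony is at or beyond the optical resolution
#'   limit; detection of such colonies is not guaranteed).
#' @param object A `SyntheticTipImage`.
#' @export
#' @exportClass SyntheticTipImage
setClass("SyntheticTipImage",
  slots = c(pixels = "matrix", optics = "OpticsProfile",
            geometry = "ConeGeometry", truth = "data.frame",
            apex = "numeric", axisAngle = "numeric", baseRadius = "numeric",
            resolutionWarning = "logical"))

#' Tip segmentation and colony-detection result
#'
#' Detected apex pixel, axis tilt and cone boundaries from
#' [segmentTip()], and (after [detectColonies()]) the detected colony
#' centres/radii in pixels and the derived axial positions in mm.
#'
#' @slot apex Detected apex `c(row, col)` px.
#' @slot axisAngle Detected tilt from vertical, degrees.
#' @slot boundaries List with `left`, `right` edge-line coefficients
#'   (col = a + b * row).
#' @slot colonies data.frame: `row_px`, `col_px`, `r_px`.
#' @slot positions Axial distances from the detected apex, mm, sorted.
#' @param object A `SegmentationResult`.
#' @export
#' @exportClass SegmentationResult
setClass("SegmentationResult",
  slots = c(apex = "numeric", axisAngle = "numeric", boundaries = "list",
            colonies = "data.frame", positions = "numeric"))

## ---- show methods ----

setMethod("show", "ConeGeometry", function(object) {
  cat(sprintf("ConeGeometry: %s, h = %g mm, V = %g uL\n",
              object@shape, object@axialLength, object@volume))
})

setMethod("show", "ColonySet", function(object) {
  cat(sprintf("ColonySet '%s': %d colonies in a %s (h = %g mm, V = %g uL), dilution %gx\n",
              object@tipId, length(object@positions),
              object@geometry@shape, object@geometry@axialLength,
              object@gelVolume, object@dilutionFactor))
  if (length(object@positions)) {
    p <- object@positions
    cat(sprintf("  axial range %.2f-%.2f mm; first from tip: %s%s\n",
                min(p), max(p),
                paste(sprintf("%.2f", utils::head(p, 5)), collapse = ", "),
                if (length(p) > 5) ", ..." else ""))
  }
})

setMethod("show", "CfuEstimate", function(object) {
  if (object@belowLod) {
    cat(sprintf("CfuEstimate: below limit of detection (< %.0f CFU/mL sample)\n",
                object@lod))
  } else {
    cat(sprintf("CfuEstimate: %.4g CFU/mL (sample), %.4g CFU/mL (gel)\n",
                object@cfuPerMlSample, object@cfuPerMlGel))
    cat(sprintf("  mode '%s', N = %d colonies counted in [%.2f, %.2f] mm\n",
                object@mode, object@nCounted, object@interval[1],
                object@interval[2]))
  }
})

setMethod("show", "SyntheticTipImage", function(object) {
  cat(sprintf("SyntheticTipImage: %d x %d px at %g um/px, %d colonies, tilt %.2f deg%s\n",
              nrow(object@pixels), ncol(object@pixels),
              object@optics@pixelSize, nrow(object@truth),
              object@axisAngle,
              if (object@resolutionWarning) " [resolution warning]" else ""))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf("SegmentationResult: apex (%.1f, %.1f) px, tilt %.2f deg, %d colonies\n",
              object@apex[1], object@apex[2], object@axisAngle,
              nrow(object@colonies)))
})

## ---- accessors ----

#' @rdname ConeGeometry-class
setMethod("axialLength", "ConeGeometry", function(geom) geom@axialLength)

#' @rdname ConeGeometry-class
setMethod("gelVolume", "ConeGeometry", function(geom) geom@volume)

#' @rdname ColonySet-class
setMethod("positions", "ColonySet", function(object) object@positions)

#' @rdname ColonySet-class
setMethod("nColonies", "ColonySet",
          function(object) length(object@positions))

#' @rdname ColonySet-class
setMethod("dilutionFactor", "ColonySet",
          function(object) object@dilutionFactor)

#' @rdname ColonySet-class
setMethod("geometry", "ColonySet", function(object) object@geometry)

#' @rdname CfuEstimate-class
setMethod("cfuPerMl", "CfuEstimate", function(object) object@cfuPerMlSample)

#' @rdname CfuEstimate-class
setMethod("isBelowLod", "CfuEstimate", function(object) object@belowLod)
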