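#' @include AllGenerics.R
NULL

#' Axial probability density of a colony position
#'
#' Density of the axial position (distance from the apex, mm) of a colony
#' seeded uniformly at random in the gel volume. For a cone (or any axially
#' symmetric pyramid) the cross-section grows as \eqn{x^2}, giving
#' \eqn{3x^2/h^3}; a wedge gives \eqn{2x/h^2} and a cylinder the uniform
#' \eqn{1/h}.
#'
#' @param geom A [ConeGeometry-class] object.
#' @param x Numeric vector of axial positions in mm, within `[0, h]`.
#' @return Numeric vector of densities (1/mm).
#' @seealso [axialCdf()], [axialQuantile()]
#' @examples
#' g <- geometryProfile("p200")
#' axialPdf(g, c(0, 18, 36))
#' @export
setGeneric("axialPdf", function(geom, x) standardGeneric("axialPdf"))

#' Axial cumulative distribution of a colony position
#'
#' Probability that a uniformly seeded colony lies within `x` mm of the
#' apex; for a cone this is \eqn{(x/h)^3}. This is the expected fraction
#' of colonies between the apex and `x`, the quantity inverted by the
#' ruler generator and used as the denominator mass of the estimator.
#'
#' @inheritParams axialPdf
#' @return Numeric vector of probabilities.
#' @examples
#' axialCdf(geometryProfile("p200"), 18)
#' @export
setGeneric("axialCdf", function(geom, x) standardGeneric("axialCdf"))

#' Axial quantile function (inverse CDF)
#'
#' Inverse of [axialCdf()]; for a cone, \eqn{x = h u^{1/3}}. Used for
#' inverse-transform sampling of colony positions.
#'
#' @param geom A [ConeGeometry-class] object.
#' @param u Numeric vector of probabilities in `[0, 1]`.
#' @return Axial positions in mm.
#' @examples
#' axialQuantile(geometryProfile("p200"), 0.125)
#' @export
setGeneric("axialQuantile", function(geom, u) standardGeneric("axialQuantile"))

#' @rdname ConeGeometry-class
#' @param object,geom A `ConeGeometry`.
#' @export
setGeneric("axialLength", function(geom) standardGeneric("axialLength"))

#' @rdname ConeGeometry-class
#' @export
setGeneric("gelVolume", function(geom) standardGeneric("gelVolume"))

#' @rdname ColonySet-class
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname ColonySet-class
#' @export
setGeneric("nColonies", function(object) standardGeneric("nColonies"))

#' @rdname ColonySet-class
#' @export
setGeneric("dilutionFactor", function(object) standardGeneric("dilutionFactor"))

#' @rdname ColonySet-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname CfuEstimate-class
#' @export
setGeneric("cfuPerMl", function(object) standardGeneric("cfuPerMl"))

#' @rdname CfuEstimate-class
#' @export
setGeneric("isBelowLod", function(object) standardGeneric("isBelowLod"))

#' Estimate CFU/mL from colony axial positions
#'
#' The core estimator: the number of colonies in the counted axial
#' interval divided by the probability mass of that interval times the
#' gel volume, rescaled to the original sample by the dilution factor.
#' See [ColonySet-class] for the input container.
#'
#' @param colonies A [ColonySet-class].
#' @param k Number of colonies to use, counted from the tip, or `"all"`.
#' @param mode Counting convention; see Details in the method.
#' @param ... Further arguments passed to methods.
#' @return A [CfuEstimate-class].
#' @export
setGeneric("estimateCfu",
           function(colonies, k = 10, mode = c("interval", "tip_anchored",
                                               "full_volume"), ...)
             standardGeneric("estimateCfu"))
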