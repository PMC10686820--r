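#' @include AllClasses.R
NULL

#' Built-in vessel geometry profiles
#'
#' Registry of named vessel profiles. `"p200"` is the standard 200 uL
#' pipette tip used for embedding: a 36 mm circular cone holding 150 uL
#' of gel.
#'
#' @param name Profile name; currently `"p200"`.
#' @return A [ConeGeometry-class].
#' @examples
#' geometryProfile("p200")
#' @export
geometryProfile <- function(name = "p200") {
  profiles <- list(
    p200 = list(shape = "circular_cone", axialLength = 36, volume = 150))
  if (!name %in% names(profiles))
    stop("unknown geometry profile '", name, "'; available: ",
         paste(names(profiles), collapse = ", "))
  p <- profiles[[name]]
  ConeGeometry(shape = p$shape, axialLength = p$axialLength,
               volume = p$volume)
}

.checkDomain <- function(v, lo, hi, what) {
  if (any(!is.finite(v)) || any(v < lo) || any(v > hi))
    stop(what, " outside [", lo, ", ", hi, "]")
}

## The axial density follows from cross-sectional area A(x) normalised by
## volume: cone/pyramid A ~ x^2, wedge A ~ x, cylinder A constant.

#' @rdname axialPdf
setMethod("axialPdf", "ConeGeometry", function(geom, x) {
  h <- geom@axialLength
  .checkDomain(x, 0, h, "axial position x (mm)")
  switch(geom@shape,
         circular_cone = ,
         square_pyramid = 3 * x^2 / h^3,
         cylinder = rep_len(1 / h, length(x)),
         wedge = 2 * x / h^2)
})

#' @rdname axialCdf
setMethod("axialCdf", "ConeGeometry", function(geom, x) {
  h <- geom@axialLength
  .checkDomain(x, 0, h, "axial position x (mm)")
  switch(geom@shape,
         circular_cone = ,
         square_pyramid = (x / h)^3,
         cylinder = x / h,
         wedge = (x / h)^2)
})

#' @rdname axialQuantile
setMethod("axialQuantile", "ConeGeometry", function(geom, u) {
  .checkDomain(u, 0, 1, "probability u")
  h <- geom@axialLength
  switch(geom@shape,
         circular_cone = ,
         square_pyramid = h * u^(1 / 3),
         cylinder = h * u,
         wedge = h * sqrt(u))
})
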