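#' @include geometry.R
NULL

#' @describeIn estimateCfu Estimate from a [ColonySet-class].
#'
#' @details
#' Three counting conventions are exposed:
#' \describe{
#'   \item{`interval` (default)}{The counted sub-volume runs from the
#'     first colony from the tip, `x1`, to the k-th colony, `x2`; the
#'     numerator counts colonies with `x1 <= x < x2` (half-open, so ties
#'     at `x2` are excluded and N = k - 1 in the generic case), and the
#'     denominator is the gel volume times the probability mass
#'     `axialCdf(x2) - axialCdf(x1)`.}
#'   \item{`tip_anchored`}{The interval is `[0, xk)` anchored at the
#'     apex, N = k - 1, mass `axialCdf(xk)`. Slightly less biased in
#'     simulation; provided as an alternative convention.}
#'   \item{`full_volume`}{The whole cone: the estimate reduces to the
#'     exhaustive count divided by gel volume (times dilution).}
#' }
#' An empty set yields a below-limit-of-detection result carrying
#' [limitOfDetection()] as an upper bound. The estimate depends only on
#' axial positions; radial coordinates are never consulted.
#'
#' @param trace Logical: also compute the running-estimate trace
#'   (see [convergenceTrace()]).
#' @examples
#' cs <- ColonySet(c(9, 18, 27), geometryProfile("p200"))
#' estimateCfu(cs, k = 3)                       # 3282 CFU/mL
#' estimateCfu(cs, k = "all", mode = "full_volume")  # 2000 CFU/mL
#' @export
setMethod("estimateCfu", "ColonySet",
          function(colonies, k = 10,
                   mode = c("interval", "tip_anchored", "full_volume"),
                   trace = FALSE, ...) {
  mode <- match.arg(mode)
  geom <- colonies@geometry
  p <- colonies@positions
  n <- length(p)
  vMl <- colonies@gelVolume / 1000          # uL -> mL
  dil <- colonies@dilutionFactor
  lod <- limitOfDetection(geom, dil, gelVolume = colonies@gelVolume)

  if (n == 0L)
    return(new("CfuEstimate", cfuPerMlSample = NA_real_,
               cfuPerMlGel = NA_real_, nCounted = 0L,
               interval = c(NA_real_, NA_real_), belowLod = TRUE,
               lod = lod, k = NA_real_, mode = mode,
               trace = data.frame(k = integer(), estimate = numeric())))

  kk <- if (identical(k, "all")) n else min(as.integer(k), n)

  if (mode == "full_volume") {
    gel <- n / vMl
    est <- new("CfuEstimate", cfuPerMlSample = gel * dil,
               cfuPerMlGel = gel, nCounted = as.integer(n),
               interval = c(0, geom@axialLength), belowLod = FALSE,
               lod = lod, k = kk, mode = mode,
               trace = data.frame(k = integer(), estimate = numeric()))
    return(est)
  }

  if (kk < 2L)
    stop("only one colony available: interval modes need >= 2 colonies; ",
         "use mode = \"full_volume\" for an exhaustive count")

  sub <- p[seq_len(kk)]
  if (mode == "interval") {
    x1 <- sub[1L]; x2 <- sub[kk]
    N <- sum(sub >= x1 & sub < x2)          # half-open: ties at x2 excluded
    mass <- axialCdf(geom, x2) - axialCdf(geom, x1)
  } else {                                   # tip_anchored
    x1 <- 0; x2 <- sub[kk]
    N <- sum(sub < x2)
    mass <- axialCdf(geom, x2)
  }
  if (mass <= 0)
    stop("degenerate counted interval [", x1, ", ", x2,
         "]: zero probability mass (coincident first and last colony)")

  gel <- N / (vMl * mass)
  tr <- if (trace) convergenceTrace(colonies, mode = mode)
        else data.frame(k = integer(), estimate = numeric())
  new("CfuEstimate", cfuPerMlSample = gel * dil, cfuPerMlGel = gel,
      nCounted = as.integer(N), interval = c(x1, x2), belowLod = FALSE,
      lod = lod, k = kk, mode = mode, trace = tr)
})

#' Running CFU estimate as colonies are added
#'
#' Recomputes the estimate using the first `k = 2, ..., n` colonies from
#' the tip, showing convergence toward the true concentration as more
#' positions are included.
#'
#' @param colonies A [ColonySet-class].
#' @param mode Counting convention, as in [estimateCfu()].
#' @return data.frame with columns `k` and `estimate` (sample-scale
#'   CFU/mL); zero rows when fewer than two colonies are present.
#' @examples
#' cs <- ColonySet(c(9, 18, 27), geometryProfile("p200"))
#' convergenceTrace(cs)
#' @export
convergenceTrace <- function(colonies, mode = c("interval", "tip_anchored")) {
  mode <- match.arg(mode)
  n <- nColonies(colonies)
  if (n < 2L)
    return(data.frame(k = integer(), estimate = numeric()))
  ks <- 2:n
  est <- vapply(ks, function(k)
    cfuPerMl(estimateCfu(colonies, k = k, mode = mode)), numeric(1))
  data.frame(k = ks, estimate = est)
}

#' Multiplicative error factor between an estimate and the truth
#'
#' `|calculated - actual| / actual + 1`: a dynamic-range-aware error
#' metric that is >= 1 and equals 1 exactly when the estimate is perfect.
#' An estimate twice (or half again above) the truth scores 2; being off
#' by a given factor scores the same at 1e3 as at 1e7 CFU/mL.
#'
#' @param calculated,actual Numeric vectors (recycled); `actual` must be
#'   positive.
#' @return Numeric vector of factors >= 1 (NA where `calculated` is NA).
#' @examples
#' factorOff(c(100, 200, 50), 100)
#' @export
factorOff <- function(calculated, actual) {
  if (any(!is.finite(actual)) || any(actual <= 0))
    stop("'actual' must be positive and finite")
  abs(calculated - actual) / actual + 1
}

#' Lower limit of detection of the embedded assay
#'
#' The smallest sample concentration observable: one colony in the
#' counted gel volume, rescaled by the embedding dilution. With the
#' standard 150 uL gel at a 1:100 dilution this is 1/0.15 mL x 100 =
#' 667 CFU/mL (to the nearest integer).
#'
#' @param geom A [ConeGeometry-class].
#' @param dilutionFactor Sample-to-gel dilution (default 100).
#' @param gelVolume Counted gel volume in uL; defaults to the geometry's
#'   volume.
#' @return Sample-scale CFU/mL (exact value; round for display).
#' @examples
#' limitOfDetection(geometryProfile("p200"), 100)  # 666.67 -> "667"
#' @export
limitOfDetection <- function(geom, dilutionFactor = 100, gelVolume = NULL) {
  if (is.null(gelVolume)) gelVolume <- geom@volume
  stopifnot(gelVolume > 0, dilutionFactor >= 1)
  1 / (gelVolume / 1000) * dilutionFactor
}
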