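#' @include robustness.R
NULL

#' Expected axial position of the k-th colony from the tip
#'
#' Inverts the cumulative axial distribution: at sample concentration
#' `c` (dilution `D`, gel volume `V`), the expected number of colonies
#' within `x` of the apex is \eqn{m (x/h)^3} with \eqn{m = cV/D}, so the
#' k-th colony is expected at \eqn{x_k = h (k/m)^{1/3}}. This is what a
#' printed ruler annotates: read the concentration off the position of
#' the k-th colony.
#'
#' `method = "order_statistic"` instead returns the median position of
#' the k-th colony under Poisson seeding (solving
#' \eqn{P(\mathrm{Pois}(m\,\mathrm{CDF}(x)) \ge k) = 1/2}); the two
#' differ by O(1/m).
#'
#' @param geom A [ConeGeometry-class].
#' @param concentration Sample-scale concentration(s), CFU/mL.
#' @param dilutionFactor Sample-to-gel dilution (default 100).
#' @param k Colony index (default 10).
#' @param method `"expected_count"` (default) or `"order_statistic"`.
#' @return Axial position(s) in mm.
#' @examples
#' kthColonyPosition(geometryProfile("p200"), 1e6)  # 6.78 mm
#' @export
kthColonyPosition <- function(geom, concentration, dilutionFactor = 100,
                              k = 10,
                              method = c("expected_count",
                                         "order_statistic")) {
  method <- match.arg(method)
  stopifnot(k >= 1, all(concentration > 0))
  vMl <- geom@volume / 1000
  m <- concentration / dilutionFactor * vMl
  if (any(m < k))
    stop("concentration too low: fewer than k = ", k,
         " colonies expected in the gel (m = ",
         paste(signif(m[m < k], 3), collapse = ", "),
         "); the k-th colony is not expected to exist")
  u <- switch(method,
              expected_count = k / m,
              order_statistic = pmin(stats::qgamma(0.5, k) / m, 1))
  axialQuantile(geom, u)
}

#' Ruler specification
#'
#' Everything needed to print a concentration ruler for a vessel: the
#' geometry, the colony index `k` to annotate, the sample-scale
#' concentrations to mark, the embedding dilution, and the page size.
#'
#' @slot geometry A [ConeGeometry-class].
#' @slot k Colony index annotated.
#' @slot concentrations Sample CFU/mL values, sorted ascending.
#' @slot dilutionFactor Sample-to-gel dilution.
#' @slot page `c(width, height)` in mm.
#' @param geometry,k,concentrations,dilutionFactor,page See slots.
#' @export RulerSpec
#' @exportClass RulerSpec
RulerSpec <- setClass("RulerSpec",
  slots = c(geometry = "ConeGeometry", k = "numeric",
            concentrations = "numeric", dilutionFactor = "numeric",
            page = "numeric"),
  prototype = list(k = 10, dilutionFactor = 100, page = c(70, 60)))

setValidity("RulerSpec", function(object) {
  msg <- character()
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (length(object@concentrations) &&
      (any(object@concentrations <= 0) ||
       is.unsorted(object@concentrations)))
    msg <- c(msg, "concentrations must be positive and sorted ascending")
  if (length(msg)) msg else TRUE
})

#' Tick table for a ruler
#'
#' Computes the annotated position for every requested concentration,
#' flagging those that cannot be annotated (expected colony count below
#' `k`) or that fall beyond the axial length.
#'
#' @param spec A [RulerSpec-class].
#' @param method Passed to [kthColonyPosition()].
#' @return data.frame: `concentration`, `x_mm` (NA when dropped),
#'   `dropped`.
#' @export
rulerTicks <- function(spec, method = "expected_count") {
  geom <- spec@geometry
  vMl <- geom@volume / 1000
  m <- spec@concentrations / spec@dilutionFactor * vMl
  x <- rep(NA_real_, length(m))
  ok <- m >= spec@k
  if (any(ok))
    x[ok] <- kthColonyPosition(geom, spec@concentrations[ok],
                               spec@dilutionFactor, spec@k, method)
  beyond <- !is.na(x) & x > geom@axialLength + 1e-9
  x[beyond] <- NA_real_
  data.frame(concentration = spec@concentrations, x_mm = x,
             dropped = !ok | beyond)
}

#' Render a printable ruler as SVG
#'
#' Writes a vector ruler at 1:1 physical scale: a vertical axis of the
#' vessel's axial length with the apex origin marked, and one tick per
#' concentration at the expected position of the k-th colony. SVG user
#' units are millimetres, so printing at 100% scale places every tick
#' with exact physical coordinates. Concentrations whose k-th colony is
#' not expected inside the vessel are dropped with a warning naming the
#' minimum annotatable concentration.
#'
#' @param spec A [RulerSpec-class].
#' @param file Output path (`.svg`).
#' @param method Passed to [kthColonyPosition()].
#' @return Invisibly, the [rulerTicks()] table.
#' @examples
#' spec <- RulerSpec(geometry = geometryProfile("p200"),
#'                   concentrations = 10^(5:9))
#' f <- tempfile(fileext = ".svg")
#' renderRuler(spec, f)
#' @export
renderRuler <- function(spec, file, method = "expected_count") {
  ticks <- rulerTicks(spec, method)
  geom <- spec@geometry
  h <- geom@axialLength
  if (any(ticks$dropped)) {
    vMl <- geom@volume / 1000
    cmin <- spec@k / vMl * spec@dilutionFactor
    warning(sum(ticks$dropped), " concentration(s) dropped; minimum ",
            "annotatable concentration is ", signif(cmin, 3), " CFU/mL")
  }
  w <- spec@page[1]; ht <- max(spec@page[2], h + 20)
  x0 <- 25                      # axis abscissa, mm from left edge
  y0 <- 10                      # apex ordinate, mm from top edge
  fmt <- function(v) sprintf("%.0e", v)   # one significant digit
  lines <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                   'width="%gmm" height="%gmm" viewBox="0 0 %g %g">'),
            w, ht, w, ht),
    '<g stroke="black" stroke-width="0.2" fill="none">',
    sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g"/>',
            x0, y0, x0, y0 + h),
    ## apex alignment origin: crosshair at the physical tip position
    sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g"/>',
            x0 - 4, y0, x0 + 4, y0),
    sprintf('<circle cx="%g" cy="%g" r="1.2"/>', x0, y0),
    '</g>',
    sprintf(paste0('<text x="%g" y="%g" font-size="3" ',
                   'font-family="sans-serif">apex (k = %g, %gx ',
                   'dilution)</text>'),
            x0 - 20, y0 - 3, spec@k, spec@dilutionFactor))
  keep <- ticks[!ticks$dropped, , drop = FALSE]
  for (i in seq_len(nrow(keep))) {
    y <- y0 + keep$x_mm[i]
    lines <- c(lines,
      sprintf(paste0('<line x1="%g" y1="%g" x2="%g" y2="%g" ',
                     'stroke="black" stroke-width="0.3"/>'),
              x0 - 3, y, x0 + 3, y),
      sprintf(paste0('<text x="%g" y="%g" font-size="3" ',
                     'font-family="sans-serif">%s</text>'),
              x0 + 5, y + 1, fmt(keep$concentration[i])))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, file)
  invisible(ticks)
}
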