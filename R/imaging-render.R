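#' @include ruler.R
NULL

#' Built-in optics profiles
#'
#' `"canon"`: mirrorless camera rig, 6.6 um pixels at the object plane.
#' `"iphone12"`: phone camera, 13.7 um pixels. Larger pixels lower the
#' maximum resolvable colony density and thereby the assay's dynamic
#' range; they do not bias the estimate where colonies remain
#' resolvable.
#'
#' @param name `"canon"` or `"iphone12"`.
#' @param ... Overrides for [OpticsProfile-class] slots.
#' @return An [OpticsProfile-class].
#' @examples
#' opticsProfile("iphone12")
#' @export
opticsProfile <- function(name = "canon", ...) {
  base <- switch(name,
                 canon = list(pixelSize = 6.6),
                 iphone12 = list(pixelSize = 13.7),
                 stop("unknown optics profile '", name, "'"))
  args <- utils::modifyList(c(base, list(noiseSd = 0, background = 0.95,
                                         rotationJitter = 0)),
                            list(...))
  do.call(OpticsProfile, args)
}

.SILHOUETTE_DROP <- 0.20   # silhouette darkening vs background
.COLONY_LEVEL <- 0.20      # rendered colony intensity (dark)

## Rendered colony radius in um: r0 at low density, shrinking as the
## cube root of density (the self-limiting colony-size rule that keeps
## colonies discrete at high densities; a stated rendering rule, not a
## growth model).
.colonyRadiusUm <- function(density, r0Um = 66, d0 = 1e5) {
  r0Um * (1 + density / d0)^(-1 / 3)
}

#' Render a synthetic image of an embedded tip
#'
#' Rasterises the cone silhouette (optionally tilted) and draws each
#' colony as a darkened disc at its axial/radial position, then adds
#' Gaussian intensity noise. Ground truth (colony positions, rendered
#' centres and radii, apex pixel, tilt) is kept on the object so
#' segmentation can be validated by round trip.
#'
#' Colony radius follows \eqn{r = r_0 (1 + \rho/d_0)^{-1/3}} with the
#' in-gel density \eqn{\rho} taken from the colony set; colonies whose
#' rendered radius falls below 2 px set `resolutionWarning`, modelling
#' the optical limit at which high-density tips stop being countable.
#'
#' @param colonies A [ColonySet-class]; radial coordinates are used when
#'   present (colonies sit on the axis otherwise).
#' @param optics An [OpticsProfile-class].
#' @param seed Optional seed (tilt jitter and noise).
#' @param baseRadius Cone base radius for the silhouette, mm.
#' @param r0Um,d0 Colony-size rule constants: radius at zero density
#'   (um) and the density scale (CFU/mL).
#' @param marginPx Blank margin around the silhouette, px.
#' @return A [SyntheticTipImage-class].
#' @examples
#' cfg <- SimulationConfig(density = 400, nReps = 1L, seed = 5,
#'                         geometry = geometryProfile("p200"))
#' cs <- sampleColonies(cfg)[[1]]
#' img <- generateTipImage(cs, OpticsProfile(pixelSize = 60))
#' @export
generateTipImage <- function(colonies, optics = opticsProfile("canon"),
                             seed = NULL, baseRadius = 2.7, r0Um = 66,
                             d0 = 1e5, marginPx = 8) {
  .setSeed(seed)
  geom <- colonies@geometry
  h <- geom@axialLength
  s <- 1000 / optics@pixelSize            # px per mm
  tilt <- if (optics@rotationJitter > 0)
    stats::runif(1, -optics@rotationJitter, optics@rotationJitter) else 0
  t <- tilt * pi / 180
  d <- c(cos(t), sin(t))                  # axis direction (row, col)
  pp <- c(-sin(t), cos(t))                # perpendicular
  hpx <- h * s
  bhw <- baseRadius * s                   # base half-width, px

  ## cone corner offsets relative to the apex
  corners <- rbind(c(0, 0), hpx * d + bhw * pp, hpx * d - bhw * pp)
  apex <- c(marginPx + 1 - min(corners[, 1]),
            marginPx + 1 - min(corners[, 2]))
  nr <- ceiling(max(corners[, 1]) - min(corners[, 1])) + 2 * marginPx + 1
  nc <- ceiling(max(corners[, 2]) - min(corners[, 2])) + 2 * marginPx + 1

  R <- matrix(seq_len(nr), nr, nc) - apex[1]
  C <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - apex[2]
  a <- R * d[1] + C * d[2]
  q <- R * pp[1] + C * pp[2]
  inside <- a >= 0 & a <= hpx & abs(q) <= pmax(a, 0) * (bhw / hpx)
  px <- matrix(optics@background, nr, nc)
  px[inside] <- optics@background - .SILHOUETTE_DROP

  n <- nColonies(colonies)
  dens <- n / (colonies@gelVolume / 1000)
  rPx <- if (n) rep(.colonyRadiusUm(dens, r0Um, d0) / optics@pixelSize, n)
         else numeric(0)
  x <- colonies@positions
  y <- if (nrow(colonies@radial)) colonies@radial[, "y_mm"]
       else rep(0, n)
  ## clip radial coordinate to the rendered silhouette
  y <- pmin(pmax(y, -baseRadius * x / h), baseRadius * x / h)
  cr <- apex[1] + x * s * d[1] + y * s * pp[1]
  cc <- apex[2] + x * s * d[2] + y * s * pp[2]
  for (i in seq_len(n)) {
    r <- rPx[i]
    rows <- max(1, floor(cr[i] - r)):min(nr, ceiling(cr[i] + r))
    cols <- max(1, floor(cc[i] - r)):min(nc, ceiling(cc[i] + r))
    if (!length(rows) || !length(cols)) next
    dd <- outer((rows - cr[i])^2, (cols - cc[i])^2, "+")
    sub <- px[rows, cols, drop = FALSE]
    sub[dd <= r^2] <- .COLONY_LEVEL
    px[rows, cols] <- sub
  }
  if (optics@noiseSd > 0)
    px <- pmin(pmax(px + stats::rnorm(length(px), 0, optics@noiseSd), 0), 1)

  warn <- n > 0 && any(rPx < 2)
  if (warn)
    warning("some colonies rendered with radius < 2 px: at or beyond ",
            "the optical resolution limit for this pixel size")
  new("SyntheticTipImage", pixels = px, optics = optics, geometry = geom,
      truth = data.frame(x_mm = x, row_px = cr, col_px = cc, r_px = rPx),
      apex = apex, axisAngle = tilt, baseRadius = baseRadius,
      resolutionWarning = warn)
}
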