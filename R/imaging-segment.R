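#' @include imaging-render.R
NULL

## Binary silhouette mask: anything clearly darker than the border
## background (silhouette and colonies both qualify).
.silhouetteMask <- function(px) {
  border <- c(px[1, ], px[nrow(px), ], px[, 1], px[, ncol(px)])
  bg <- stats::median(border)
  ## any clear darkening vs the border background counts as silhouette
  ## (colonies are darker still and are included); the margin tolerates
  ## mild noise without swallowing the background
  thr <- bg - max(0.04, 6 * stats::mad(border))
  mask <- px < thr
  if (!any(mask)) stop("no tip silhouette found in the image")
  mask
}

#' Locate the tip apex and axis in an image
#'
#' Finds the cone silhouette, estimates the axis tilt from the
#' silhouette's principal axis, refines it with the left/right edge
#' lines of the cone, and intersects those edges to locate the apex.
#' On noise-free synthetic images the apex is recovered within 2 px and
#' the tilt within 0.5 degrees.
#'
#' @param image A [SyntheticTipImage-class] or a numeric intensity
#'   matrix.
#' @return A [SegmentationResult-class] (colony slots empty).
#' @examples
#' cs <- ColonySet(c(10, 20), geometryProfile("p200"))
#' img <- generateTipImage(cs, OpticsProfile(pixelSize = 80))
#' segmentTip(img)
#' @export
segmentTip <- function(image) {
  px <- if (is(image, "SyntheticTipImage")) image@pixels else image
  mask <- .silhouetteMask(px)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  Z <- sweep(idx, 2, ctr)
  ev <- eigen(crossprod(Z) / nrow(Z), symmetric = TRUE)
  v <- ev$vectors[, 1]                     # major axis
  if (v[1] < 0) v <- -v                    # point roughly downward
  tproj <- Z %*% v
  wproj <- Z %*% c(-v[2], v[1])
  ## the apex end of the axis is the narrow end
  qs <- stats::quantile(tproj, c(0.15, 0.85))
  if (stats::sd(wproj[tproj < qs[1]]) > stats::sd(wproj[tproj > qs[2]])) {
    v <- -v
    tproj <- -tproj
  }
  pvec <- c(-v[2], v[1])
  wproj <- Z %*% pvec

  ## edge lines: extreme perpendicular offset in one-pixel axial bins
  ## over the mid-section (avoids the rounded apex and the base end),
  ## pushed half a pixel outward: within a 1-px bin the extreme pixel
  ## centre sits U(0,1) px inside the true edge, so -0.5 is unbiased
  tr <- range(tproj)
  bin <- floor(tproj)
  mid <- bin >= tr[1] + 0.25 * diff(tr) & bin <= tr[1] + 0.9 * diff(tr)
  lo <- tapply(wproj[mid], bin[mid], min) - 0.5
  hi <- tapply(wproj[mid], bin[mid], max) + 0.5
  tb <- as.numeric(names(lo)) + 0.5
  edges <- data.frame(t = tb, lo = as.numeric(lo), hi = as.numeric(hi))
  ## trimmed refit: colonies overhanging the silhouette edge produce
  ## locally widened bins; drop large-residual bins and refit
  robustLine <- function(y, t) {
    fit <- stats::lm(y ~ t)
    for (i in 1:2) {
      keep <- abs(stats::resid(fit)) <= 1.5
      if (all(keep) || sum(keep) < 10) break
      fit <- stats::lm(y[keep] ~ t[keep])
      y <- y[keep]; t <- t[keep]
    }
    fit
  }
  fitL <- robustLine(edges$lo, edges$t)
  fitR <- robustLine(edges$hi, edges$t)
  aL <- stats::coef(fitL)[1]; bL <- stats::coef(fitL)[2]
  aR <- stats::coef(fitR)[1]; bR <- stats::coef(fitR)[2]
  ## intersection of the two edges = apex (in axis coordinates)
  tApex <- unname((aR - aL) / (bL - bR))
  wApex <- unname(aL + bL * tApex)
  apex <- ctr + tApex * v + wApex * pvec
  ## the edge bisector corrects the PCA axis for residual asymmetry
  dTheta <- atan((bL + bR) / 2)
  angle <- (atan2(v[2], v[1]) + dTheta) * 180 / pi
  new("SegmentationResult", apex = unname(apex), axisAngle = angle,
      boundaries = list(left = c(intercept = unname(aL), slope = unname(bL)),
                        right = c(intercept = unname(aR), slope = unname(bR)),
                        centroid = unname(ctr), axis = unname(v)),
      colonies = data.frame(row_px = numeric(), col_px = numeric(),
                            r_px = numeric()),
      positions = numeric(0))
}

## Scale-normalised Laplacian-of-Gaussian kernel; responds positively
## to dark discs on a bright background of radius ~ sigma * sqrt(2).
.logKernel <- function(sigma) {
  sz <- max(3L, 2L * ceiling(3 * sigma) + 1L)
  ax <- seq_len(sz) - (sz + 1) / 2
  d2 <- outer(ax^2, ax^2, "+")
  g <- exp(-d2 / (2 * sigma^2))
  g <- g / sum(g)
  k <- (2 * sigma^2 - d2) / sigma^2 * g    # sigma^2-normalised -LoG
  k - mean(k)                              # zero response to flat areas
}

.localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  res <- matrix(TRUE, nr, nc)
  pad <- function(dr, dc) {
    out <- matrix(-Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    okr <- rs >= 1 & rs <= nr; okc <- cs >= 1 & cs <= nc
    out[okr, okc] <- m[rs[okr], cs[okc]]
    out
  }
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    res <- res & (m >= pad(dr, dc))
  }
  res
}

#' Detect colonies in a tip image
#'
#' Multi-scale blob detection: the image is inverted (colonies are dark
#' discs), convolved with scale-normalised Laplacian-of-Gaussian kernels
#' over a geometric scale ladder, and blobs are taken as local maxima of
#' the response that exceed `threshold`, keeping each blob at its
#' best-responding scale and suppressing overlaps. Detections are
#' restricted to the cone silhouette and to the analysed axial window.
#'
#' `level` selects how far from the apex the analysis reaches: levels
#' 1-5 cover the apex-most 1, 1/2, 1/5, 1/10 and 1/20 of the axial
#' length; level 5 additionally caps the result at the first 30
#' colonies. Narrow windows suit dense tips where only the colonies
#' nearest the apex are countable.
#'
#' A curation hook mirrors semi-automated use: `add` is a data.frame of
#' `row_px`, `col_px` (optional `r_px`) appended as detections; `remove`
#' is a data.frame of coordinates whose nearest detection is deleted.
#'
#' @param image A [SyntheticTipImage-class] or numeric matrix.
#' @param segmentation A [SegmentationResult-class] from [segmentTip()];
#'   computed when NULL.
#' @param level Axial zoom level, 1-5.
#' @param pixelSize Pixel size in um (taken from the image's optics when
#'   available).
#' @param threshold Minimum LoG response (intensity units).
#' @param sigmas Scale ladder; defaults to a geometric sequence covering
#'   radii from ~2 px to a quarter of the base width.
#' @param axialLength Axial length in mm (needed for windows beyond
#'   level 1 when `image` is a bare matrix).
#' @param add,remove Curation edits (see Details).
#' @return A [SegmentationResult-class] with colony centres, radii and
#'   sorted axial positions in mm.
#' @examples
#' cfg <- SimulationConfig(density = 300, nReps = 1L, seed = 11,
#'                         geometry = geometryProfile("p200"))
#' img <- generateTipImage(sampleColonies(cfg)[[1]],
#'                         OpticsProfile(pixelSize = 60))
#' det <- detectColonies(img)
#' nrow(det@colonies)
#' @export
detectColonies <- function(image, segmentation = NULL, level = 1,
                           pixelSize = NULL, threshold = 0.15,
                           sigmas = NULL, axialLength = NULL,
                           add = NULL, remove = NULL) {
  px <- if (is(image, "SyntheticTipImage")) image@pixels else image
  if (is.null(pixelSize)) {
    if (!is(image, "SyntheticTipImage"))
      stop("pixelSize is required when 'image' is a bare matrix")
    pixelSize <- image@optics@pixelSize
  }
  if (!level %in% 1:5) stop("level must be 1..5")
  if (is.null(segmentation)) segmentation <- segmentTip(px)
  mask <- .silhouetteMask(px)

  t <- segmentation@axisAngle * pi / 180
  d <- c(cos(t), sin(t)); pvec <- c(-sin(t), cos(t))
  apex <- segmentation@apex

  inv <- max(px) - px                     # colonies become bright
  if (is.null(sigmas)) {
    ## scale ladder up to ~half the base half-width (largest credible
    ## colony), geometric steps of sqrt(2)
    widths <- tapply(which(mask, arr.ind = TRUE)[, 2],
                     which(mask, arr.ind = TRUE)[, 1], function(v)
                       diff(range(v)))
    rmax <- max(4, max(widths) / 4)
    sigmas <- unique(2^seq(0.5, log2(max(2.1, rmax / sqrt(2))),
                           by = 0.5))
  }
  resp <- lapply(sigmas, function(sg)
    EBImage::filter2(inv, .logKernel(sg)))
  best <- Reduce(pmax, resp)
  ## intensity gate: a true colony centre is much darker than the
  ## silhouette, while edge artefacts of the response are not
  silLevel <- stats::median(px[mask])
  darkest <- min(px[mask])
  intGate <- if (silLevel - darkest > 0.1)
    px < silLevel - 0.5 * (silLevel - darkest)
  else mask & FALSE
  cand <- which(.localMaxima(best) & best > threshold & mask & intGate,
                arr.ind = TRUE)
  if (nrow(cand)) {
    val <- best[cand]
    sgAt <- vapply(seq_len(nrow(cand)), function(i) {
      rs <- vapply(resp, function(r) r[cand[i, 1], cand[i, 2]], numeric(1))
      sigmas[which.max(rs)]
    }, numeric(1))
    rad <- sgAt * sqrt(2)
    ## greedy non-maximum suppression of overlapping blobs
    ord <- order(val, decreasing = TRUE)
    keep <- logical(nrow(cand))
    for (i in ord) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      kk <- which(keep)
      dist <- sqrt((cand[kk, 1] - cand[i, 1])^2 +
                   (cand[kk, 2] - cand[i, 2])^2)
      if (all(dist > 0.75 * (rad[kk] + rad[i]))) keep[i] <- TRUE
    }
    det <- data.frame(row_px = cand[keep, 1], col_px = cand[keep, 2],
                      r_px = rad[keep])
  } else {
    det <- data.frame(row_px = numeric(), col_px = numeric(),
                      r_px = numeric())
  }

  if (!is.null(add) && nrow(add)) {
    if (is.null(add$r_px)) add$r_px <- stats::median(det$r_px)
    det <- rbind(det, add[, c("row_px", "col_px", "r_px")])
  }
  if (!is.null(remove) && nrow(remove) && nrow(det)) {
    for (i in seq_len(nrow(remove))) {
      if (!nrow(det)) break
      dd <- (det$row_px - remove$row_px[i])^2 +
            (det$col_px - remove$col_px[i])^2
      det <- det[-which.min(dd), , drop = FALSE]
    }
  }

  ## axial positions via projection onto the detected axis
  aPx <- (det$row_px - apex[1]) * d[1] + (det$col_px - apex[2]) * d[2]
  posMm <- aPx * pixelSize / 1000
  frac <- c(1, 1 / 2, 1 / 5, 1 / 10, 1 / 20)[level]
  if (is(image, "SyntheticTipImage")) {
    hMm <- image@geometry@axialLength
  } else if (!is.null(axialLength)) {
    hMm <- axialLength
  } else if (level == 1L) {
    hMm <- Inf
  } else {
    stop("axialLength is required for level > 1 with a bare matrix")
  }
  inWin <- posMm >= -0.5 & posMm <= frac * hMm + 1e-9
  det <- det[inWin, , drop = FALSE]
  posMm <- pmax(posMm[inWin], 0)
  ord <- order(posMm)
  det <- det[ord, , drop = FALSE]
  posMm <- posMm[ord]
  if (level == 5L && length(posMm) > 30L) {
    det <- det[1:30, , drop = FALSE]
    posMm <- posMm[1:30]
  }
  rownames(det) <- NULL
  new("SegmentationResult", apex = segmentation@apex,
      axisAngle = segmentation@axisAngle,
      boundaries = segmentation@boundaries, colonies = det,
      positions = posMm)
}

#' End-to-end estimate from a tip image
#'
#' Segments the tip, detects colonies, converts their axial positions to
#' mm and feeds them to [estimateCfu()] — the full loop from pixels to
#' CFU/mL. Empty detections yield a below-limit-of-detection result.
#'
#' @param image A [SyntheticTipImage-class] (or numeric matrix, with
#'   `geometry` and `pixelSize` supplied).
#' @param geometry A [ConeGeometry-class]; taken from the image when
#'   available.
#' @param dilutionFactor Sample-to-gel dilution.
#' @param k Colonies to use (capped at the detection count).
#' @param level Axial zoom level for [detectColonies()].
#' @param pixelSize,threshold Passed to [detectColonies()].
#' @return A [CfuEstimate-class].
#' @examples
#' cfg <- SimulationConfig(density = 300, nReps = 1L, seed = 11,
#'                         geometry = geometryProfile("p200"))
#' img <- generateTipImage(sampleColonies(cfg)[[1]],
#'                         OpticsProfile(pixelSize = 60))
#' imageToEstimate(img)
#' @export
imageToEstimate <- function(image, geometry = NULL, dilutionFactor = 100,
                            k = 10, level = 1, pixelSize = NULL,
                            threshold = 0.06) {
  if (is.null(geometry)) {
    if (!is(image, "SyntheticTipImage"))
      stop("geometry is required when 'image' is a bare matrix")
    geometry <- image@geometry
  }
  det <- detectColonies(image, level = level, pixelSize = pixelSize,
                        threshold = threshold)
  pos <- pmin(pmax(det@positions, 0), geometry@axialLength)
  cs <- ColonySet(pos, geometry, tipId = "image",
                  dilutionFactor = dilutionFactor)
  n <- nColonies(cs)
  if (n == 0L) return(estimateCfu(cs))
  if (n == 1L) return(estimateCfu(cs, mode = "full_volume"))
  estimateCfu(cs, k = min(k, n))
}
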