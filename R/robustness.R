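#' @include simulator.R
NULL

#' Keep only the first n colonies from the tip
#'
#' Truncates a [ColonySet-class] to the `n` colonies nearest the apex —
#' the "counted" subset that perturbation experiments corrupt.
#'
#' @param colonies A [ColonySet-class].
#' @param n Number of colonies to keep.
#' @return A [ColonySet-class] with at most `n` colonies.
#' @export
headColonies <- function(colonies, n) {
  idx <- seq_len(min(n, nColonies(colonies)))
  ColonySet(colonies@positions[idx], colonies@geometry,
            tipId = colonies@tipId,
            dilutionFactor = colonies@dilutionFactor,
            gelVolume = colonies@gelVolume,
            radial = if (nrow(colonies@radial))
              colonies@radial[idx, , drop = FALSE] else NULL)
}

#' Remove colonies from a counted set
#'
#' Emulates missed colonies: removes `nMissing` colonies from the set
#' under a removal policy. `uniform_random` (the default) drops colonies
#' at random; `nearest_tip_first` drops those closest to the apex (the
#' worst case, since it moves the counted interval's anchor);
#' `farthest_first` drops from the base end.
#'
#' @param colonies A [ColonySet-class] (typically [headColonies()] of a
#'   simulated tip).
#' @param spec A [PerturbationSpec-class], or `nMissing` given directly.
#' @param nMissing,removalPolicy Used when `spec` is missing.
#' @param seed Optional seed for the random policy.
#' @return A [ColonySet-class] with `nMissing` fewer colonies, still
#'   sorted.
#' @examples
#' cs <- ColonySet(c(3, 9, 18, 27, 30), geometryProfile("p200"))
#' dropColonies(cs, nMissing = 2, seed = 1)
#' @export
dropColonies <- function(colonies, spec = NULL, nMissing = 0,
                         removalPolicy = "uniform_random", seed = NULL) {
  if (!is.null(spec)) {
    nMissing <- spec@nMissing
    removalPolicy <- spec@removalPolicy
  }
  n <- nColonies(colonies)
  if (n - nMissing < 2L)
    stop("cannot drop ", nMissing, " of ", n,
         " colonies: at least 2 must remain for interval estimation")
  if (nMissing == 0L) return(colonies)
  .setSeed(seed)
  drop <- switch(removalPolicy,
                 uniform_random = sample.int(n, nMissing),
                 nearest_tip_first = seq_len(nMissing),
                 farthest_first = seq.int(n - nMissing + 1L, n),
                 stop("unknown removalPolicy '", removalPolicy, "'"))
  keep <- setdiff(seq_len(n), drop)
  ColonySet(colonies@positions[keep], colonies@geometry,
            tipId = colonies@tipId,
            dilutionFactor = colonies@dilutionFactor,
            gelVolume = colonies@gelVolume,
            radial = if (nrow(colonies@radial))
              colonies@radial[keep, , drop = FALSE] else NULL)
}

#' Displace the assumed apex position
#'
#' Emulates misidentifying the tip position: every axial position is
#' shifted by `tipOffset` mm (positive = the apex was assumed farther
#' from the colonies than it is, so all measured distances grow) and
#' clipped to `[0, h]`. The geometry is unchanged.
#'
#' @param colonies A [ColonySet-class].
#' @param tipOffset Signed offset in mm; `|tipOffset|` must be smaller
#'   than the axial length.
#' @return The shifted [ColonySet-class].
#' @examples
#' cs <- ColonySet(c(9, 18, 27), geometryProfile("p200"))
#' positions(offsetTip(cs, 4))
#' @export
offsetTip <- function(colonies, tipOffset) {
  h <- colonies@geometry@axialLength
  if (abs(tipOffset) >= h)
    stop("|tipOffset| must be smaller than the axial length (", h, " mm)")
  if (tipOffset == 0) return(colonies)
  x <- pmin(pmax(colonies@positions + tipOffset, 0), h)
  ColonySet(x, colonies@geometry, tipId = colonies@tipId,
            dilutionFactor = colonies@dilutionFactor,
            gelVolume = colonies@gelVolume,
            radial = if (nrow(colonies@radial)) colonies@radial else NULL)
}

#' Coefficient of variation among replicate estimates
#'
#' The technical-noise measure: sample standard deviation over mean of
#' replicate CFU/mL estimates, on the linear scale.
#'
#' @param estimates Numeric vector (>= 2 positive values).
#' @return The CV (dimensionless).
#' @examples
#' replicateCv(c(800, 1200))
#' @export
replicateCv <- function(estimates) {
  if (length(estimates) < 2L)
    stop("need at least 2 replicate estimates")
  if (any(!is.finite(estimates)) || any(estimates <= 0))
    stop("all replicate estimates must be positive and finite")
  stats::sd(estimates) / mean(estimates)
}

#' Paired sweep over missed-colony and tip-offset perturbations
#'
#' For each density, simulates `nReps` cones once and re-estimates the
#' same cones under every combination of missing-colony count and apex
#' offset, so perturbation effects are compared on identical colony
#' configurations. Each cone contributes its first `nCounted` colonies;
#' after removing `n_missing` of them uniformly at random and shifting
#' by `offset_mm`, the estimate uses the first `min(k, survivors)`
#' remaining colonies under the default interval convention.
#'
#' Replicates with fewer than `nCounted` colonies, or whose perturbed
#' interval is degenerate, are excluded from that cell's summary
#' (`n_tips` reports the survivors).
#'
#' @param densities In-gel densities, CFU/mL.
#' @param missingGrid Integer vector of `n_missing` values.
#' @param offsetGrid Numeric vector of apex offsets, mm.
#' @param nCounted Colonies counted per cone before perturbation.
#' @param k Colonies used for the estimate.
#' @param nReps Replicate cones per density.
#' @param geometry A [ConeGeometry-class].
#' @param seed Master seed.
#' @return data.frame: `density`, `n_missing`, `offset_mm`,
#'   `mean_factor_off`, `sd_factor_off`, `n_tips`.
#' @examples
#' errorSweep(1e4, missingGrid = c(0, 5), offsetGrid = 0, nReps = 200,
#'            seed = 3)
#' @export
errorSweep <- function(densities, missingGrid = 0, offsetGrid = 0,
                       nCounted = 15, k = 10, nReps = 1000,
                       geometry = geometryProfile("p200"), seed = NULL) {
  if (!length(missingGrid) || !length(offsetGrid))
    stop("missingGrid and offsetGrid must be nonempty")
  if (any(missingGrid < 0) || any(missingGrid > nCounted - 2L))
    stop("n_missing must lie in [0, nCounted - 2]")
  h <- geometry@axialLength
  if (any(abs(offsetGrid) >= h))
    stop("|offset| must be smaller than the axial length")
  .setSeed(seed)
  vMl <- geometry@volume / 1000
  out <- list()
  for (d in densities) {
    sim <- .simulateFirstK(d, geometry, nCounted, nReps)
    ok <- sim$N >= nCounted
    X <- sim$X[ok, , drop = FALSE]
    nOk <- nrow(X)
    ## one drop pattern per (replicate, n_missing), shared across offsets
    keepSets <- lapply(missingGrid, function(m) {
      if (m == 0L) {
        matrix(rep(seq_len(nCounted), each = nOk), nrow = nOk)
      } else {
        t(vapply(seq_len(nOk), function(i)
          sort(sample.int(nCounted, nCounted - m)),
          integer(nCounted - m)))
      }
    })
    for (mi in seq_along(missingGrid)) {
      m <- missingGrid[mi]
      keep <- keepSets[[mi]]
      nSurv <- ncol(keep)
      S <- matrix(X[cbind(rep(seq_len(nOk), nSurv), as.vector(keep))],
                  nrow = nOk)
      kk <- min(k, nSurv)
      for (o in offsetGrid) {
        Ss <- pmin(pmax(S + o, 0), h)
        x1 <- Ss[, 1L]; x2 <- Ss[, kk]
        mass <- axialCdf(geometry, x2) - axialCdf(geometry, x1)
        Nc <- rowSums(Ss[, seq_len(kk), drop = FALSE] < x2) # half-open
        est <- ifelse(mass > 0, Nc / (vMl * mass), NA_real_)
        fo <- factorOff(est, d)
        fo <- fo[is.finite(fo)]
        out[[length(out) + 1L]] <- data.frame(
          density = d, n_missing = m, offset_mm = o,
          mean_factor_off = if (length(fo)) mean(fo) else NA_real_,
          sd_factor_off = if (length(fo) > 1) stats::sd(fo) else NA_real_,
          n_tips = length(fo))
      }
    }
  }
  do.call(rbind, out)
}
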