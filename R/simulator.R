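#' @include estimator.R
NULL

#' Simulation study configuration
#'
#' Conditions for simulating embedded tips: the true in-gel colony
#' density, the vessel geometry, the number of replicate cones, the
#' master RNG seed and the dilution factor used when reporting on the
#' sample scale.
#'
#' @slot density True in-gel density, CFU/mL.
#' @slot geometry A [ConeGeometry-class].
#' @slot nReps Replicate cones.
#' @slot seed Master seed (NA = leave the RNG alone).
#' @slot dilutionFactor Sample-to-gel dilution for reporting.
#' @param density,geometry,nReps,seed,dilutionFactor See slots.
#' @export SimulationConfig
#' @exportClass SimulationConfig
SimulationConfig <- setClass("SimulationConfig",
  slots = c(density = "numeric", geometry = "ConeGeometry",
            nReps = "integer", seed = "numeric",
            dilutionFactor = "numeric"),
  prototype = list(density = 1e4, nReps = 1L, seed = NA_real_,
                   dilutionFactor = 100))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@density < 0) msg <- c(msg, "density must be >= 0")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (length(msg)) msg else TRUE
})

.setSeed <- function(seed) {
  if (!is.null(seed) && length(seed) == 1L && is.finite(seed))
    set.seed(as.integer(seed))
  invisible(NULL)
}

## Colony counts are Poisson with mean density x volume; axial positions
## are i.i.d. with CDF (x/h)^3, drawn by inverse transform x = h u^(1/3).
.sampleOneCone <- function(density, geom, dilutionFactor, tipId,
                           radial = TRUE, baseRadius = 2.7) {
  vMl <- geom@volume / 1000
  n <- stats::rpois(1L, density * vMl)
  u <- sort(stats::runif(n))
  x <- axialQuantile(geom, u)
  rad <- NULL
  if (radial && n > 0) {
    rmax <- baseRadius * x / geom@axialLength
    r <- rmax * sqrt(stats::runif(n))
    phi <- stats::runif(n, 0, 2 * pi)
    rad <- cbind(y_mm = r * cos(phi), z_mm = r * sin(phi))
  }
  ColonySet(x, geom, tipId = tipId, dilutionFactor = dilutionFactor,
            radial = rad)
}

#' Simulate colony configurations in replicate cones
#'
#' Draws each cone's colony count from a Poisson law with mean
#' density x gel volume, and colony axial positions i.i.d. from the
#' cone's axial distribution by inverse-transform sampling. Radial
#' coordinates (uniform over the cross-sectional disc at each axial
#' position, base radius `baseRadius` mm) are attached for the imaging
#' module; the estimator never reads them.
#'
#' Replicate cones use independent substreams derived from the master
#' seed, so a replicate's colonies are reproducible regardless of how
#' many replicates are drawn.
#'
#' @param config A [SimulationConfig-class].
#' @param radial Attach radial coordinates? Default TRUE.
#' @param baseRadius Cone base radius used for radial sampling, mm.
#' @return A list of [ColonySet-class], length `nReps(config)`.
#' @examples
#' cfg <- SimulationConfig(density = 1e4, geometry = geometryProfile("p200"),
#'                         nReps = 2L, seed = 7)
#' sets <- sampleColonies(cfg)
#' vapply(sets, nColonies, integer(1))
#' @export
sampleColonies <- function(config, radial = TRUE, baseRadius = 2.7) {
  stopifnot(is(config, "SimulationConfig"))
  .setSeed(config@seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, config@nReps)
  lapply(seq_len(config@nReps), function(i) {
    set.seed(repSeeds[i])
    .sampleOneCone(config@density, config@geometry, config@dilutionFactor,
                   tipId = sprintf("sim%04d", i), radial = radial,
                   baseRadius = baseRadius)
  })
}

## First k order statistics of N i.i.d. uniforms without materialising
## all N draws: the exact sequential recursion
##   v_j = 1 - (1 - v_{j-1}) * W^(1/(N - j + 1)),  W ~ U(0,1),
## vectorised over replicates. Columns j > N_i are NA. O(k) per cone,
## which makes 1,000-replicate studies at 1e7 CFU/mL (1.5e6 colonies
## per cone) feasible.
.firstKUniforms <- function(N, k) {
  reps <- length(N)
  U <- matrix(NA_real_, reps, k)
  v <- numeric(reps)
  for (j in seq_len(k)) {
    alive <- N >= j
    if (!any(alive)) break
    w <- stats::runif(sum(alive))
    v[alive] <- 1 - (1 - v[alive]) * w^(1 / (N[alive] - j + 1))
    U[alive, j] <- v[alive]
  }
  U
}

## Matrix of the first k axial positions (mm) for nReps simulated cones.
## Returns list(N = counts, X = positions matrix, U = cdf values).
.simulateFirstK <- function(density, geom, k, nReps) {
  vMl <- geom@volume / 1000
  N <- stats::rpois(nReps, density * vMl)
  U <- .firstKUniforms(N, k)
  list(N = N, X = axialQuantile(geom, ifelse(is.na(U), 0, U)) *
         NA^is.na(U), U = U)
}

## Interval-mode gel-scale estimate from cdf values of the first k
## colonies (continuous positions: N = k - 1 in the half-open interval).
.intervalEstimateGel <- function(u1, uk, k, vMl) {
  (k - 1) / (vMl * (uk - u1))
}

#' Convergence of the estimator with the number of counted colonies
#'
#' Simulates replicate cones at each density and summarises the
#' multiplicative error ([factorOff()]) of the estimate computed from
#' the first `k` colonies, for `k = 2, ..., kMax`. Replicates holding
#' fewer than `k` colonies are excluded from that `k`'s summary (the
#' conditioning rate is reported as `n_used / nReps`).
#'
#' @param densities In-gel densities, CFU/mL.
#' @param kMax Largest number of colonies to include.
#' @param nReps Replicate cones per density.
#' @param geometry A [ConeGeometry-class].
#' @param seed Master seed.
#' @return data.frame: `density`, `k`, `n_used`, `mean_factor_off`,
#'   `sd_factor_off`, `frac_within_2`. Rows where no replicate reached
#'   `k` colonies carry NA summaries.
#' @examples
#' convergenceExperiment(1e4, kMax = 10, nReps = 200, seed = 1)
#' @export
convergenceExperiment <- function(densities, kMax = 15, nReps = 1000,
                                  geometry = geometryProfile("p200"),
                                  seed = NULL) {
  stopifnot(kMax >= 2, nReps >= 1)
  .setSeed(seed)
  vMl <- geometry@volume / 1000
  out <- lapply(densities, function(d) {
    sim <- .simulateFirstK(d, geometry, kMax, nReps)
    do.call(rbind, lapply(2:kMax, function(k) {
      ok <- sim$N >= k
      if (!any(ok))
        return(data.frame(density = d, k = k, n_used = 0L,
                          mean_factor_off = NA_real_,
                          sd_factor_off = NA_real_,
                          frac_within_2 = NA_real_))
      est <- .intervalEstimateGel(sim$U[ok, 1L], sim$U[ok, k], k, vMl)
      fo <- factorOff(est, d)
      data.frame(density = d, k = k, n_used = sum(ok),
                 mean_factor_off = mean(fo), sd_factor_off = stats::sd(fo),
                 frac_within_2 = mean(fo < 2))
    }))
  })
  do.call(rbind, out)
}

#' Simulated dilution-series linearity
#'
#' Simulates replicate cones along a geometric dilution series, estimates
#' each cone, averages replicate estimates per step after taking log10,
#' and fits an ordinary least-squares regression of mean log-estimate on
#' log true density. A slope of 1 means the estimate scales linearly
#' with dilution.
#'
#' @param baseDensity Starting in-gel density, CFU/mL.
#' @param fold Dilution factor per step (> 1).
#' @param nSteps Number of dilution steps (>= 2).
#' @param nReps Replicate cones per step.
#' @param k Colonies used per estimate (all colonies when a cone holds
#'   fewer; single-colony cones fall back to the exhaustive count;
#'   empty cones are dropped, a step with no survivors is dropped with a
#'   warning).
#' @param geometry A [ConeGeometry-class].
#' @param seed Master seed.
#' @return List: `table` (density, mean_log10_estimate, n_used),
#'   `slope`, `intercept`, `r_squared`, and the `lm` fit.
#' @examples
#' res <- dilutionSeriesExperiment(1e6, fold = 4, nSteps = 5, nReps = 4,
#'                                 seed = 2)
#' res$slope
#' @export
dilutionSeriesExperiment <- function(baseDensity = 1e7, fold = 4,
                                     nSteps = 8, nReps = 4, k = 10,
                                     geometry = geometryProfile("p200"),
                                     seed = NULL) {
  if (nSteps < 2) stop("a regression needs at least two dilution steps")
  if (fold <= 1) stop("'fold' must exceed 1 (a constant series has no slope)")
  .setSeed(seed)
  dens <- baseDensity / fold^(seq_len(nSteps) - 1)
  rows <- lapply(dens, function(d) {
    cfg <- SimulationConfig(density = d, geometry = geometry,
                            nReps = as.integer(nReps), seed = NA_real_,
                            dilutionFactor = 1)
    ests <- vapply(seq_len(nReps), function(i) {
      cs <- .sampleOneCone(d, geometry, 1, sprintf("d%g_r%d", d, i),
                           radial = FALSE)
      n <- nColonies(cs)
      if (n == 0L) return(NA_real_)
      if (n == 1L) return(cfuPerMl(estimateCfu(cs, mode = "full_volume")))
      cfuPerMl(estimateCfu(cs, k = min(k, n)))
    }, numeric(1))
    ests <- ests[is.finite(ests) & ests > 0]
    data.frame(density = d, mean_log10_estimate =
                 if (length(ests)) mean(log10(ests)) else NA_real_,
               n_used = length(ests))
  })
  tab <- do.call(rbind, rows)
  dropped <- is.na(tab$mean_log10_estimate)
  if (any(dropped)) {
    warning(sum(dropped), " dilution step(s) produced no colonies and were dropped")
    tab <- tab[!dropped, , drop = FALSE]
  }
  if (nrow(tab) < 2) stop("fewer than two usable dilution steps")
  fit <- stats::lm(mean_log10_estimate ~ log10(density), data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, fit = fit)
}
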