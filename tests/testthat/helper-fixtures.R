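# Shared fixtures: everything is generated in code at test time.

p200 <- geometryProfile("p200")

# Thin a simulated colony set so that no two colonies are closer than
# minSepMm in the imaging projection (axial, lateral). Rendered discs
# then never merge, which is the regime where the detection round trip
# promises exact counts.
separatedColonySet <- function(density, seed, minSepMm = 1.2,
                               geometry = p200) {
  cfg <- SimulationConfig(density = density, geometry = geometry,
                          nReps = 1L, seed = seed)
  cs <- sampleColonies(cfg)[[1]]
  p <- positions(cs)
  y <- if (nrow(cs@radial)) cs@radial[, "y_mm"] else rep(0, length(p))
  keep <- logical(length(p))
  for (i in seq_along(p)) {
    kk <- which(keep)
    if (!length(kk) ||
        all(sqrt((p[kk] - p[i])^2 + (y[kk] - y[i])^2) > minSepMm))
      keep[i] <- TRUE
  }
  ColonySet(p[keep], geometry, tipId = cs@tipId,
            dilutionFactor = dilutionFactor(cs),
            radial = cs@radial[keep, , drop = FALSE])
}

# Coarse optics used throughout the imaging tests: 60 um pixels keep a
# full-length p200 render at ~620 x 110 px.
testOptics <- function(...) OpticsProfile(pixelSize = 60, ...)

# Renderer settings giving ~6.7 px colonies at these coarse pixels.
testR0Um <- 400
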