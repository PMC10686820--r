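test_that("dropping zero colonies is the identity; policies remove the right ones", {
  cs <- ColonySet(c(3, 9, 18, 27, 30), p200)
  expect_identical(positions(dropColonies(cs, nMissing = 0)),
                   positions(cs))
  near <- dropColonies(cs, nMissing = 2,
                       removalPolicy = "nearest_tip_first")
  expect_identical(positions(near), c(18, 27, 30))
  far <- dropColonies(cs, nMissing = 2, removalPolicy = "farthest_first")
  expect_identical(positions(far), c(3, 9, 18))
  rnd <- dropColonies(cs, nMissing = 2, seed = 4)
  expect_length(positions(rnd), 3L)
  expect_false(is.unsorted(positions(rnd)))
  expect_error(dropColonies(cs, nMissing = 4), "at least 2")
})

test_that("a perturbation spec of (0 missing, 0 offset) reproduces the input exactly", {
  cs <- separatedColonySet(200, seed = 8)
  spec <- PerturbationSpec(nMissing = 0L, tipOffset = 0)
  out <- offsetTip(dropColonies(cs, spec), spec@tipOffset)
  expect_identical(positions(out), positions(cs))
  expect_identical(cfuPerMl(estimateCfu(out, k = 5)),
                   cfuPerMl(estimateCfu(cs, k = 5)))
})

test_that("tip offsets shift, clip and validate", {
  cs <- ColonySet(c(2, 9, 34), p200)
  expect_identical(positions(offsetTip(cs, 0)), positions(cs))
  expect_equal(positions(offsetTip(cs, 4)), c(6, 13, 36))   # clipped at h
  expect_equal(positions(offsetTip(cs, -4)), c(0, 5, 30))   # clipped at 0
  expect_error(offsetTip(cs, 36), "smaller than")
})

test_that("replicate CV matches hand values and is scale invariant", {
  expect_equal(replicateCv(rep(1000, 4)), 0)
  expect_equal(replicateCv(c(800, 1200)), sd(c(800, 1200)) / 1000)
  expect_equal(round(replicateCv(c(800, 1200)), 4), 0.2828)
  x <- c(500, 900, 1300)
  expect_equal(replicateCv(17 * x), replicateCv(x))
  expect_error(replicateCv(1000), "at least 2")
  expect_error(replicateCv(c(-1, 5)), "positive")
})

test_that("replicate noise shrinks as density grows (Poisson counting)", {
  set.seed(61)
  cvAt <- function(d) {
    cfg <- SimulationConfig(density = d, geometry = p200, nReps = 40L,
                            seed = d)
    ests <- vapply(sampleColonies(cfg, radial = FALSE), function(cs) {
      n <- nColonies(cs)
      if (n < 2) return(NA_real_)
      cfuPerMl(estimateCfu(cs, k = min(10, n)))
    }, numeric(1))
    replicateCv(ests[is.finite(ests)])
  }
  # quadruplicate-style noise, 40 reps for a stable CV estimate
  expect_gt(cvAt(100), cvAt(1e5) * 0.9)
})

test_that("error sweep: unperturbed cell matches baseline; error grows with missing colonies", {
  sw10 <- errorSweep(1e4, missingGrid = 0, offsetGrid = 0,
                     nCounted = 15, k = 10, nReps = 600, seed = 17)
  base <- convergenceExperiment(1e4, kMax = 10, nReps = 600, seed = 90)
  b10 <- base$mean_factor_off[base$k == 10]
  expect_lt(abs(sw10$mean_factor_off - b10), 0.1)  # same statistic

  # re-estimating from all survivors: error is nondecreasing in the
  # number of missed colonies (within one Monte-Carlo s.e.)
  sw <- errorSweep(1e4, missingGrid = c(0, 4, 8, 10), offsetGrid = 0,
                   nCounted = 15, k = 15, nReps = 1000, seed = 17)
  mcse <- max(sw$sd_factor_off / sqrt(sw$n_tips))
  expect_true(all(diff(sw$mean_factor_off) > -mcse))
  expect_gt(sw$mean_factor_off[4], sw$mean_factor_off[1])
})

test_that("high densities are more sensitive to tip offset than low densities", {
  sw <- errorSweep(c(1e3, 1e7), missingGrid = 0, offsetGrid = c(0, 4),
                   nReps = 600, seed = 23)
  off <- sw[sw$offset_mm == 4, ]
  expect_gt(off$mean_factor_off[off$density == 1e7],
            off$mean_factor_off[off$density == 1e3])
  # and offset hurts relative to no offset at fixed density
  at7 <- sw[sw$density == 1e7, ]
  expect_gt(at7$mean_factor_off[at7$offset_mm == 4],
            at7$mean_factor_off[at7$offset_mm == 0])
})

test_that("error sweep validates its grids", {
  expect_error(errorSweep(1e4, missingGrid = integer(0)), "nonempty")
  expect_error(errorSweep(1e4, missingGrid = 14, nCounted = 15),
               "n_missing")
  expect_error(errorSweep(1e4, offsetGrid = 40), "axial length")
})
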