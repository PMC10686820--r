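test_that("the interval estimator reproduces the hand-worked example", {
  cs <- ColonySet(c(9, 18, 27), p200, dilutionFactor = 100)
  e <- estimateCfu(cs, k = 3)
  # N = 2 in [9, 27), mass = (27^3 - 9^3)/36^3 = 0.40625
  expect_equal(cfuPerMl(e), 2 / (0.15 * 0.40625) * 100, tolerance = 1e-12)
  expect_equal(e@nCounted, 2L)
  expect_equal(e@interval, c(9, 27))
  expect_equal(e@cfuPerMlGel * 100, cfuPerMl(e))

  full <- estimateCfu(cs, k = "all", mode = "full_volume")
  expect_equal(cfuPerMl(full), 3 / 0.15 * 100)
})

test_that("edge cases: empty set, single colony, degenerate interval", {
  empty <- ColonySet(numeric(0), p200)
  e <- estimateCfu(empty)
  expect_true(isBelowLod(e))
  expect_true(is.na(cfuPerMl(e)))
  expect_equal(e@lod, 1 / 0.15 * 100)

  one <- ColonySet(18, p200)
  expect_error(estimateCfu(one, k = 2), "full_volume")
  expect_equal(cfuPerMl(estimateCfu(one, mode = "full_volume")),
               1 / 0.15 * 100)

  ties <- ColonySet(c(12, 12, 12), p200)
  expect_error(estimateCfu(ties, k = 3), "degenerate")
})

test_that("convergence trace agrees with per-k estimates and handles tiny sets", {
  cs <- ColonySet(c(9, 18, 27), p200)
  tr <- convergenceTrace(cs)
  expect_equal(tr$k, 2:3)
  expect_equal(tr$estimate[2], cfuPerMl(estimateCfu(cs, k = 3)))
  expect_equal(tr$estimate[1], cfuPerMl(estimateCfu(cs, k = 2)))
  expect_equal(nrow(convergenceTrace(ColonySet(18, p200))), 0L)
})

test_that("the factor-off metric behaves as a multiplicative error", {
  expect_equal(factorOff(100, 100), 1)
  expect_equal(factorOff(200, 100), 2)
  expect_equal(factorOff(50, 100), 1.5)
  expect_equal(factorOff(c(100, 400), c(100, 100)), c(1, 4))
  expect_error(factorOff(100, 0), "positive")
  expect_error(factorOff(100, -5), "positive")
})

test_that("limit of detection arithmetic", {
  expect_equal(round(limitOfDetection(p200, 100)), 667)
  g1 <- ConeGeometry("circular_cone", axialLength = 50, volume = 1000)
  expect_equal(limitOfDetection(g1, 1), 1)
  expect_equal(limitOfDetection(p200, 1), 1 / 0.15)
})

test_that("full-volume mode equals count over volume times dilution, exactly", {
  set.seed(101)
  for (i in 1:20) {
    n <- rpois(1, 30)
    cs <- ColonySet(sort(runif(n, 0, 36)), p200,
                    dilutionFactor = sample(c(1, 10, 100), 1))
    e <- estimateCfu(cs, k = "all", mode = "full_volume")
    if (n == 0) expect_true(isBelowLod(e))
    else expect_identical(cfuPerMl(e),
                          n / 0.15 * dilutionFactor(cs))
  }
})

test_that("estimates are invariant to radial coordinates, bit for bit", {
  set.seed(7)
  x <- sort(runif(12, 0, 36))
  rad <- cbind(runif(12, -2, 2), runif(12, -2, 2))
  a <- estimateCfu(ColonySet(x, p200), k = 10)
  b <- estimateCfu(ColonySet(x, p200, radial = rad), k = 10)
  expect_identical(cfuPerMl(a), cfuPerMl(b))
  expect_identical(a@interval, b@interval)
})

test_that("dilution factor scales the sample estimate exactly", {
  x <- sort(runif(8, 0, 36))
  e1 <- estimateCfu(ColonySet(x, p200, dilutionFactor = 1), k = 8)
  e50 <- estimateCfu(ColonySet(x, p200, dilutionFactor = 50), k = 8)
  expect_identical(cfuPerMl(e50), 50 * cfuPerMl(e1))
  expect_identical(e1@cfuPerMlGel, e50@cfuPerMlGel)
})

test_that("interval probability mass is positive and widens monotonically", {
  g <- p200
  x <- sort(runif(10, 1, 35))
  masses <- vapply(2:10, function(k)
    axialCdf(g, x[k]) - axialCdf(g, x[1]), numeric(1))
  expect_true(all(masses > 0))
  expect_true(all(diff(masses) >= 0))
})

test_that("tip-anchored mode uses the apex-anchored interval", {
  cs <- ColonySet(c(9, 18, 27), p200, dilutionFactor = 1)
  e <- estimateCfu(cs, k = 3, mode = "tip_anchored")
  expect_equal(cfuPerMl(e), 2 / (0.15 * (27 / 36)^3), tolerance = 1e-12)
  expect_equal(e@interval, c(0, 27))
})
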