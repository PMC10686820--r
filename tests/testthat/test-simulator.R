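test_that("zero density yields empty colony sets", {
  cfg <- SimulationConfig(density = 0, geometry = p200, nReps = 3L,
                          seed = 1)
  sets <- sampleColonies(cfg)
  expect_length(sets, 3L)
  expect_true(all(vapply(sets, nColonies, integer(1)) == 0L))
})

test_that("identical seed and config reproduce colony sets bit for bit", {
  cfg <- SimulationConfig(density = 5e3, geometry = p200, nReps = 4L,
                          seed = 99)
  a <- sampleColonies(cfg)
  b <- sampleColonies(cfg)
  for (i in seq_along(a)) {
    expect_identical(positions(a[[i]]), positions(b[[i]]))
    expect_identical(a[[i]]@radial, b[[i]]@radial)
  }
})

test_that("colony counts follow the Poisson law in mean and variance", {
  set.seed(11)
  m <- 2000 * 0.15                                  # 300 expected
  cfg <- SimulationConfig(density = 2000, geometry = p200,
                          nReps = 1000L, seed = 11)
  n <- vapply(sampleColonies(cfg, radial = FALSE), nColonies, integer(1))
  seMean <- sqrt(m / 1000)
  expect_lt(abs(mean(n) - m), 4 * seMean)
  seVar <- m * sqrt(2 / 999)                        # approx se of var
  expect_lt(abs(var(n) - m), 4 * seVar)
})

test_that("axial positions follow the cubic law (KS distance < 0.01 at 1e5 draws)", {
  set.seed(5)
  pooled <- numeric(0)
  # pool whole cones only: positions within a cone are sorted, so
  # truncating mid-cone would bias the pooled sample
  while (length(pooled) < 1e5) {
    cs <- gva:::.sampleOneCone(2e4, p200, 1, "t", radial = FALSE)
    pooled <- c(pooled, positions(cs))
  }
  u <- sort(axialCdf(p200, pooled))
  ks <- max(abs(u - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.01)
})

test_that("the sequential first-k sampler matches brute-force order statistics", {
  # oracle: sort all N uniforms and keep the first k
  set.seed(21)
  reps <- 3000; N <- 40L; k <- 5L
  brute <- t(replicate(reps, sort(runif(N))[1:k]))
  fast <- gva:::.firstKUniforms(rep(N, reps), k)
  for (j in c(1L, 3L, k)) {
    p <- suppressWarnings(ks.test(brute[, j], fast[, j]))$p.value
    expect_gt(p, 1e-4)
  }
  # exact marginal means: E U_(j) = j / (N + 1)
  expect_equal(colMeans(fast), (1:k) / (N + 1), tolerance = 0.02)
})

test_that("the fast experiment path agrees with the estimator on a concrete set", {
  x <- c(2.1, 5.7, 8.3, 11.9, 14.2)
  cs <- ColonySet(x, p200, dilutionFactor = 1)
  direct <- cfuPerMl(estimateCfu(cs, k = 5))
  u <- axialCdf(p200, x)
  fast <- gva:::.intervalEstimateGel(u[1], u[5], 5, 0.15)
  expect_equal(direct, fast, tolerance = 1e-12)
})

test_that("the estimate converges as more colonies are included", {
  tab <- convergenceExperiment(1e4, kMax = 10, nReps = 500, seed = 31)
  m2 <- tab$mean_factor_off[tab$k == 2]
  m10 <- tab$mean_factor_off[tab$k == 10]
  expect_gt(m2, m10)
  expect_lt(m10, 2)
  expect_true(all(tab$n_used <= 500))
})

test_that("dilution series regression recovers unit slope and rejects degenerate input", {
  res <- dilutionSeriesExperiment(1e6, fold = 4, nSteps = 6, nReps = 4,
                                  seed = 13)
  expect_lt(abs(res$slope - 1), 0.1)
  expect_gt(res$r_squared, 0.98)
  expect_error(dilutionSeriesExperiment(1e6, fold = 4, nSteps = 1),
               "two dilution steps")
  expect_error(dilutionSeriesExperiment(1e6, fold = 1, nSteps = 5),
               "fold")
})
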