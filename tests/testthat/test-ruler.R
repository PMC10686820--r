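test_that("k-th colony position inverts the cumulative law", {
  # m = 1500 expected colonies: x10 = 36 * (10/1500)^(1/3)
  expect_equal(kthColonyPosition(p200, 1e6, 100, 10),
               36 * (10 / 1500)^(1 / 3), tolerance = 1e-12)
  # m = k puts the k-th colony at the base
  cAtBase <- 10 / 0.15 * 100
  expect_equal(kthColonyPosition(p200, cAtBase, 100, 10), 36)
  # doubling the concentration divides x_k by 2^(1/3)
  x1 <- kthColonyPosition(p200, 1e6)
  x2 <- kthColonyPosition(p200, 2e6)
  expect_equal(x1 / x2, 2^(1 / 3), tolerance = 1e-12)
  expect_error(kthColonyPosition(p200, 1000, 100, 10), "too low")
})

test_that("tick positions are monotone in concentration and in k", {
  conc <- 10^seq(5, 9, by = 0.5)
  x <- kthColonyPosition(p200, conc)
  expect_true(all(diff(x) < 0))
  xs <- vapply(c(1, 5, 10, 20), function(k)
    kthColonyPosition(p200, 1e7, k = k), numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("the order-statistic variant stays within O(1/m) of expected-count inversion", {
  xE <- kthColonyPosition(p200, 1e6, k = 10)
  xO <- kthColonyPosition(p200, 1e6, k = 10, method = "order_statistic")
  expect_lt(abs(xE - xO) / xE, 0.05)
})

test_that("ruler ticks drop unannotatable concentrations with a warning", {
  spec <- RulerSpec(geometry = p200,
                    concentrations = c(1e3, 1e5, 1e6, 1e7))
  ticks <- rulerTicks(spec)
  expect_true(ticks$dropped[1])              # 1e3: m = 1.5 < 10
  expect_false(any(ticks$dropped[-1]))
  f <- withr::local_tempfile(fileext = ".svg")
  expect_warning(renderRuler(spec, f), "minimum")
  expect_true(file.exists(f))
})

test_that("the rendered SVG is at 1:1 physical scale with one tick per concentration", {
  spec <- RulerSpec(geometry = p200, concentrations = 10^(5:9))
  f <- withr::local_tempfile(fileext = ".svg")
  ticks <- renderRuler(spec, f)
  svg <- readLines(f)
  expect_match(svg[1], 'width="[0-9.]+mm"')
  # one labelled tick per concentration, positions monotone toward apex
  expect_equal(sum(grepl("e\\+0", svg)), 5)
  expect_false(any(ticks$dropped))
  expect_true(all(diff(ticks$x_mm) < 0))
  # tick y coordinates embed apex offset + x_mm exactly
  expect_true(any(grepl(sprintf('y1="%g"', 10 + ticks$x_mm[1]), svg)))
})

test_that("simulated k-th colony positions agree with the annotated tick", {
  set.seed(41)
  k <- 10
  for (conc in c(5e5, 2e6)) {                # m = 750 and 3000 >= 3k
    m <- conc / 100 * 0.15
    N <- rpois(5000, m)
    U <- gva:::.firstKUniforms(N, k)
    xk <- axialQuantile(p200, U[, k][N >= k])
    tick <- kthColonyPosition(p200, conc, 100, k)
    expect_lt(abs(mean(xk) - tick) / tick, 0.05)
  }
})

test_that("reading a tip with the ruler recovers the concentration within one tick", {
  # 4x-spaced ticks; the observed 10th colony is assigned the nearest
  # tick (in log-position); >= 90% of cones land on the true tick
  set.seed(43)
  k <- 10
  tickConc <- 1e5 * 4^(0:6)
  tickPos <- kthColonyPosition(p200, tickConc, 100, k)
  trueConc <- 1e5 * 4^3
  m <- trueConc / 100 * 0.15
  N <- rpois(2000, m)
  U <- gva:::.firstKUniforms(N, k)
  xk <- axialQuantile(p200, U[, k][N >= k])
  assigned <- vapply(xk, function(x)
    tickConc[which.min(abs(log(tickPos) - log(x)))], numeric(1))
  expect_gte(mean(assigned == trueConc), 0.9)
})
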