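test_that("an empty colony set renders a silhouette-only image", {
  img <- generateTipImage(ColonySet(numeric(0), p200), testOptics())
  expect_s4_class(img, "SyntheticTipImage")
  expect_equal(nrow(img@truth), 0L)
  expect_false(img@resolutionWarning)
  lv <- sort(unique(as.vector(img@pixels)))
  expect_length(lv, 2L)                     # background and silhouette
})

test_that("rendered colony centres lie inside the cone silhouette", {
  cs <- separatedColonySet(200, seed = 2)
  img <- generateTipImage(cs, testOptics(), r0Um = testR0Um)
  h <- axialLength(p200)
  s <- 1000 / img@optics@pixelSize
  a <- img@truth$row_px - img@apex[1]       # tilt 0: axial = rows
  q <- img@truth$col_px - img@apex[2]
  expect_true(all(a >= 0 & a <= h * s + 1e-9))
  expect_true(all(abs(q) <= a * (img@baseRadius * s) / (h * s) + 1e-9))
})

test_that("coarser pixels trigger the resolution warning that finer pixels avoid", {
  # 20 um colonies: 3 px at 6.6 um/px but 1.5 px at 13.7 um/px
  small <- ConeGeometry("circular_cone", axialLength = 6, volume = 2)
  cfg <- SimulationConfig(density = 4000, geometry = small, nReps = 1L,
                          seed = 3)
  cs <- sampleColonies(cfg)[[1]]
  expect_gt(nColonies(cs), 0)
  fine <- generateTipImage(cs, opticsProfile("canon"), r0Um = 20)
  expect_false(fine@resolutionWarning)
  expect_warning(
    coarse <- generateTipImage(cs, opticsProfile("iphone12"), r0Um = 20),
    "resolution")
  expect_true(coarse@resolutionWarning)
})

test_that("tip segmentation recovers apex and tilt on noise-free images", {
  for (jitter in c(0, 3)) {
    img <- generateTipImage(ColonySet(numeric(0), p200),
                            testOptics(rotationJitter = jitter), seed = 5)
    seg <- segmentTip(img)
    expect_lt(abs(seg@axisAngle - img@axisAngle), 0.5)
    expect_lt(sqrt(sum((seg@apex - img@apex)^2)), 2)
  }
  expect_error(segmentTip(matrix(0.95, 50, 50)), "silhouette")
})

test_that("detection round trip: exact counts, positions within 2 px", {
  for (s in c(1, 4, 9)) {
    cs <- separatedColonySet(150, seed = s)
    img <- generateTipImage(cs, testOptics(), r0Um = testR0Um)
    det <- detectColonies(img)
    expect_identical(nrow(det@colonies), nColonies(cs))
    tol <- 2 * img@optics@pixelSize / 1000
    expect_lt(max(abs(sort(det@positions) - positions(cs))), tol)
  }
})

test_that("zoom windows restrict the axial range and level 5 caps at 30", {
  img <- generateTipImage(ColonySet(numeric(0), p200), testOptics())
  seg <- segmentTip(img)
  s <- 1000 / img@optics@pixelSize
  # 35 fakes inside the apex-most h/20 (30 px), 5 well beyond h/2
  fake <- data.frame(
    row_px = img@apex[1] + c(seq(3, 28, length.out = 35),
                             seq(340, 560, length.out = 5)),
    col_px = img@apex[2], r_px = 3)
  det5 <- detectColonies(img, segmentation = seg, level = 5, add = fake,
                         threshold = 2)   # threshold 2: no real maxima
  expect_identical(length(det5@positions), 30L)   # capped
  expect_true(all(det5@positions <= 36 / 20 + 1e-6))
  det2 <- detectColonies(img, segmentation = seg, level = 2, add = fake,
                         threshold = 2)
  expect_true(all(det2@positions <= 36 / 2 + 1e-6))
  expect_equal(length(det2@positions), 35L)   # the far 5 are beyond h/2
})

test_that("curation can add and remove detections", {
  cs <- separatedColonySet(150, seed = 4)
  img <- generateTipImage(cs, testOptics(), r0Um = testR0Um)
  det <- detectColonies(img)
  n <- nrow(det@colonies)
  plus <- detectColonies(img, add = data.frame(row_px = 30, col_px =
    img@apex[2], r_px = 4))
  expect_identical(nrow(plus@colonies), n + 1L)
  minus <- detectColonies(img, remove = det@colonies[1, c("row_px",
    "col_px")])
  expect_identical(nrow(minus@colonies), n - 1L)
})

test_that("image-to-estimate closes the loop and flags empty tips", {
  fos <- vapply(c(2, 6, 8), function(s) {
    cs <- separatedColonySet(150, seed = s)
    img <- generateTipImage(cs, testOptics(), r0Um = testR0Um)
    direct <- cfuPerMl(estimateCfu(cs, k = min(10, nColonies(cs))))
    fromImage <- cfuPerMl(imageToEstimate(img))
    factorOff(fromImage, direct)
  }, numeric(1))
  expect_true(all(fos < 1.2))   # pixel-level position error only

  empty <- generateTipImage(ColonySet(numeric(0), p200), testOptics())
  expect_true(isBelowLod(imageToEstimate(empty)))
})

test_that("estimates are invariant to a small in-plane rotation", {
  cs <- separatedColonySet(150, seed = 12)
  flat <- generateTipImage(cs, testOptics(), r0Um = testR0Um)
  tilted <- generateTipImage(cs, testOptics(rotationJitter = 2.5),
                             seed = 14, r0Um = testR0Um)
  expect_gt(abs(tilted@axisAngle), 0.5)     # actually tilted
  eF <- cfuPerMl(imageToEstimate(flat))
  eT <- cfuPerMl(imageToEstimate(tilted))
  expect_lt(factorOff(eT, eF), 1.15)
})
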