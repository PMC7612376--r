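test_that("simulated SAXS noise is seed-deterministic and well calibrated", {
  q <- qGridLin(80)
  cyl <- cylinderIntensity(19, 1.9, q)
  a <- simulateSAXS(cyl, noiseModel(seed = 5))
  b <- simulateSAXS(cyl, noiseModel(seed = 5))
  expect_identical(a@I, b@I)
  expect_false(identical(a@I, simulateSAXS(cyl, noiseModel(seed = 6))@I))
  # relative_sd = 0 with a negligible floor approaches the identity
  clean <- simulateSAXS(cyl, noiseModel(relativeSd = 0, floorSd = 1e-12,
                                        seed = 1))
  expect_equal(clean@I, cyl@I, tolerance = 1e-9)
  # the declared sigma matches the generating noise: chi2 ~ 1
  chis <- vapply(1:200, function(i) {
    obs <- simulateSAXS(cyl, noiseModel(seed = i))
    chi2Fit(cyl, obs)$chi2
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 0.1)
})

test_that("SEC mixtures are pointwise convex combinations of species", {
  q <- qGridLin(60)
  mix <- list(list(
    list(spec = fibreModelSpec(subunitSpec("TWO_TWO"), 2L), fraction = 0.3),
    list(spec = fibreModelSpec(subunitSpec("FOUR_FOUR"), 1L), fraction = 0.7)))
  rec <- secSeriesRecipe(mix, q, noiseModel(relativeSd = 0, floorSd = 1e-12,
                                            seed = 1))
  frame <- simulateSECSeries(rec)[[1]]
  I1 <- debyeIntensity(buildFibreBeads(fibreModelSpec(subunitSpec("TWO_TWO"), 2L)), q)@I
  I2 <- debyeIntensity(buildFibreBeads(fibreModelSpec(subunitSpec("FOUR_FOUR"), 1L)), q)@I
  expect_equal(frame@I, 0.3 * I1 + 0.7 * I2, tolerance = 1e-6)
  expect_true(all(frame@I >= pmin(I1, I2) - 1e-6 &
                  frame@I <= pmax(I1, I2) + 1e-6))
  expect_error(secSeriesRecipe(list(list(list(
    spec = fibreModelSpec(subunitSpec("TWO_TWO"), 1L), fraction = 0.5))),
    q), "sum to 1")
})

test_that("micrograph generation is deterministic and truth-consistent", {
  rec <- micrographRecipe(sizePx = 256, counts = c("2:2-fibre" = 2L),
                          seed = 42)
  a <- simulateMicrograph(rec)
  b <- simulateMicrograph(rec)
  expect_identical(pixelMatrix(a$image), pixelMatrix(b$image))
  expect_identical(a$truth, b$truth)
  # re-rendering the truth polylines reproduces the noise-free field
  fieldA <- renderFibreField(a$polylines, a$truth$widthNm / 0.5, 256, 1)
  fieldB <- renderFibreField(b$polylines, b$truth$widthNm / 0.5, 256, 1)
  expect_identical(fieldA, fieldB)
  # truth lengths equal polyline arc lengths
  arc <- vapply(a$polylines, FibreForge:::.polyLength, numeric(1)) * 0.5
  expect_equal(a$truth$lengthNm, arc)
  # zero fibres: pure background, no detections
  none <- simulateMicrograph(micrographRecipe(sizePx = 256,
                                              counts = c("2:2-fibre" = 0L),
                                              noiseSd = 0, bgAmplitude = 0,
                                              seed = 1))
  expect_equal(length(detectRidges(none$image, sigma = 2)), 0L)
  expect_error(micrographRecipe(sizePx = 64), "too small")
})
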