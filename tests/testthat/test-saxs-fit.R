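test_that("Guinier analysis is exact on a Gaussian curve and a sphere", {
  q <- seq(0.002, 0.05, by = 0.001)
  gf <- guinierFit(saxsCurve(q, exp(-q^2 * 49^2 / 3)))
  expect_equal(gf@Rg, 4.9, tolerance = 1e-6)
  expect_equal(gf@I0, 1, tolerance = 1e-6)
  expect_lte(gf@maxQRg, 1.3)
  sph <- sphereCurve(3, qGridLog(150))
  expect_equal(guinierFit(sph)@Rg, sqrt(3 / 5) * 3, tolerance = 0.01)
  # rising curve has no Guinier region
  expect_error(guinierFit(saxsCurve(q, exp(q^2 * 100))), "non-negative")
  expect_error(guinierFit(saxsCurve(q[1:4], exp(-q[1:4]^2))), "insufficient")
})

test_that("cylinder Guinier suite recovers the closed-form Rg and Rc", {
  q <- qGridLog(250, 0.002, 0.35)
  for (L in c(15, 19, 35, 65)) for (R in c(1.0, 1.7, 2.7)) {
    cyl <- cylinderIntensity(L, R, q)
    expect_equal(guinierFit(cyl)@Rg, cylRg(L, R), tolerance = 0.03,
                 label = sprintf("Rg L=%g R=%g", L, R))
    expect_equal(crossSectionFit(cyl)@Rc, R / sqrt(2), tolerance = 0.03,
                 label = sprintf("Rc L=%g R=%g", L, R))
  }
  # the 2:2 calibration: R = 1.7 nm reproduces the 1.2-nm rod radius
  rc22 <- crossSectionFit(cylinderIntensity(19, 1.7, q))@Rc
  expect_equal(round(rc22, 1), 1.2)
  # the 4:4 calibration: R = 2.69 nm gives 1.9 nm
  rc44 <- crossSectionFit(cylinderIntensity(19, 2.69, q))@Rc
  expect_equal(round(rc44, 1), 1.9)
})

test_that("cross-section fit handles the exact 1/q rod limit", {
  q <- qGridLog(100)
  cf <- crossSectionFit(saxsCurve(q, 1 / q), Rg = 20)
  expect_equal(cf@Rc, 0)
})

test_that("chi-square fitting recovers scale and expectation", {
  q <- seq(0.01, 0.2, by = 0.002)
  model <- saxsCurve(q, exp(-30 * q))
  data <- saxsCurve(q, 3.7 * exp(-30 * q), sigma = rep(0.01, length(q)))
  fit <- chi2Fit(model, data)
  expect_equal(fit$scale, 3.7, tolerance = 1e-9)
  expect_equal(fit$chi2, 0, tolerance = 1e-12)
  # noise realizations: mean reduced chi2 ~ 1 within 0.1 over 200 repeats
  chis <- withr::with_seed(11, vapply(1:200, function(i) {
    s <- 0.05 * model@I
    noisy <- saxsCurve(q, model@I + rnorm(length(q), 0, s), sigma = s)
    chi2Fit(model, noisy)$chi2
  }, numeric(1)))
  expect_lt(abs(mean(chis) - 1), 0.1)
  # mismatched model fits worse than the generating model
  wrong <- saxsCurve(q, exp(-60 * q))
  noisy <- withr::with_seed(3, saxsCurve(q, model@I * (1 + rnorm(length(q), 0, 0.05)),
                                         sigma = 0.05 * model@I))
  expect_gt(chi2Fit(wrong, noisy)$chi2, chi2Fit(model, noisy)$chi2)
  expect_error(chi2Fit(model, saxsCurve(q, model@I)), "sigma")
})
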