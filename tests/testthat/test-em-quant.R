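# Detection, measurement and population statistics on synthetic fibres.
# The heavier end-to-end fixtures are generated once and reused.

test_that("preprocessing removes backgrounds and passes the band", {
  const <- micrograph(matrix(3.7, 128, 128), 0.5)
  out <- preprocessMicrograph(const, bgScale = 16, bandSmall = 2,
                              bandLarge = 30)
  expect_true(all(pixelMatrix(out) == 0))
  # additive linear gradient leaves the interior essentially unchanged
  base <- straightFibreImage(size = 128, w = 8, lengthPx = 80)$image
  grad <- outer(seq_len(128), seq_len(128), function(y, x) 0.002 * x + 0.001 * y)
  withGrad <- micrograph(pixelMatrix(base) + grad, 0.5)
  pA <- pixelMatrix(preprocessMicrograph(base, 16, 2, 30))[33:96, 33:96]
  pB <- pixelMatrix(preprocessMicrograph(withGrad, 16, 2, 30))[33:96, 33:96]
  expect_lt(max(abs(pA - pB)) / diff(range(pA)), 0.05)
  # sinusoid in the band survives; long-period sinusoid is strongly cut
  xx <- outer(rep(1, 128), seq_len(128))
  inBand <- micrograph(sin(2 * pi * xx / 10), 0.5)
  outBand <- micrograph(sin(2 * pi * xx / 100), 0.5)
  ampl <- function(im) {
    p <- pixelMatrix(preprocessMicrograph(im, 16, 2, 30,
                                          standardize = FALSE))[, 33:96]
    diff(range(p)) / 2
  }
  expect_gt(ampl(inBand), 0.8)
  expect_lt(ampl(outBand), 0.8 / 10)
  expect_error(preprocessMicrograph(const, 16, 40, 20), "bandSmall")
})

test_that("a blank image yields no ridges", {
  blank <- micrograph(matrix(0.5, 128, 128), 0.5)
  expect_length(detectRidges(blank, sigma = 2), 0L)
})

test_that("widths and lengths are recovered on noise-free fibres", {
  for (w in c(4, 8, 12, 20)) {
    fx <- straightFibreImage(size = 256, w = w)
    tr <- detectRidges(fx$image, sigma = w / (2 * sqrt(3)), minLength = 30)
    expect_length(tr, 1L)
    lenPx <- tr[[1]]@length / 0.5
    widPx <- tr[[1]]@meanWidth / 0.5
    expect_lt(abs(lenPx - 200) / 200, 0.05,
              label = sprintf("length w=%d", w))
    expect_lt(abs(widPx - w) / w, 0.10, label = sprintf("width w=%d", w))
  }
})

test_that("measurements are rotation equivariant within 3%", {
  base <- straightFibreImage(size = 256, w = 8, angle = 0)
  rot <- straightFibreImage(size = 256, w = 8, angle = 37)
  sigma <- 8 / (2 * sqrt(3))
  t0 <- detectRidges(base$image, sigma = sigma, minLength = 30)[[1]]
  t37 <- detectRidges(rot$image, sigma = sigma, minLength = 30)[[1]]
  expect_lt(abs(t37@length - t0@length) / t0@length, 0.03)
  expect_lt(abs(t37@meanWidth - t0@meanWidth) / t0@meanWidth, 0.03)
})

test_that("two parallel fibres separated by more than 4 sigma are resolved", {
  size <- 256; w <- 6; sigma <- w / (2 * sqrt(3))
  sep <- ceiling(4 * sigma) + w
  polys <- list(rbind(c(40, 128 - sep / 2), c(216, 128 - sep / 2)),
                rbind(c(40, 128 + sep / 2), c(216, 128 + sep / 2)))
  field <- renderFibreField(polys, c(w, w), size, 1)
  im <- micrograph(0.5 - field, 0.5, "DARK_RIDGES")
  tr <- detectRidges(im, sigma = sigma, minLength = 30)
  expect_length(tr, 2L)
})

test_that("detection count matches ground truth for non-overlapping fibres
           in at least 95% of 50 repeats", {
  ok <- 0L
  for (sd in 1:50) {
    rec <- micrographRecipe(sizePx = 384,
                            counts = c("2:2-fibre" = 2L, "4:4-fibre" = 2L),
                            seed = sd)
    sim <- simulateMicrograph(rec)
    qn <- quantifyMicrograph(sim$image, expectedWidthNm = 4, k = 0,
                             minLengthNm = 20)
    ok <- ok + (nrow(qn$fibres) == nrow(sim$truth))
  }
  expect_gte(ok / 50, 0.95)
})

test_that("fibre tables, histograms and taxonomy gating are consistent", {
  expect_equal(nrow(measureFibres(list(), 0.5)), 0L)
  tr <- detectRidges(straightFibreImage(size = 256, w = 8)$image,
                     sigma = 2.3, minLength = 30)
  tab <- measureFibres(tr, 0.5, minLengthNm = 15)
  expect_named(tab, c("id", "length_nm", "mean_width_nm", "n_points"))
  expect_equal(tab$length_nm, 100, tolerance = 0.05)

  h <- widthHistogram(c(2.3, 2.4, 3.6), bin = 0.5)
  expect_equal(h$count[h$lower == 2.0], 2)
  expect_equal(h$count[h$lower == 3.5], 1)
  expect_equal(sum(h$count), 3)
  expect_equal(nrow(widthHistogram(numeric(), 0.5)), 0L)
  expect_equal(sum(widthHistogram(c(0.3, 0.4), 5)$count), 2)
})

test_that("Gaussian mixture fitting separates the 2-nm and 4-nm classes", {
  # k = 1 returns the sample moments exactly
  w1 <- c(1.8, 2.2, 2.0, 2.4)
  f1 <- fitWidthPopulations(w1, k = 1)
  expect_equal(f1$mean, mean(w1))
  expect_equal(f1$sd, sd(w1))
  expect_equal(f1$n, 4L)
  expect_error(fitWidthPopulations(rep(2, 10), k = 2), "degenerate")
  # two-class mixture at the taxonomy means with the observed population
  # spreads: hard assignments match truth for >= 85% of fibres
  truthCls <- rep(1:2, each = 120)
  w <- withr::with_seed(8, c(rnorm(120, 2, 0.4), rnorm(120, 4, 1.0)))
  w <- pmax(w, 0.5)
  fit <- fitWidthPopulations(w, k = 2)
  expect_equal(sum(fit$n), 240L)
  expect_lt(abs(fit$mean[1] - 2) / 2, 0.1)
  expect_lt(abs(fit$mean[2] - 4) / 4, 0.1)
  acc <- mean(attr(fit, "classification") == truthCls)
  expect_gte(acc, 0.85)
  # well separated populations: means within 10% of truth
  wsep <- withr::with_seed(9, c(rnorm(60, 2, 0.25), rnorm(60, 6, 0.25)))
  fsep <- fitWidthPopulations(wsep, k = 2)
  expect_lt(abs(fsep$mean[1] - 2), 0.2)
  expect_lt(abs(fsep$mean[2] - 6), 0.6)
})
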