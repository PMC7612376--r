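# Shared fixtures: small grids and models used across test files.

qGridLog <- function(n = 200, qmin = 0.002, qmax = 0.35)
  exp(seq(log(qmin), log(qmax), length.out = n))

qGridLin <- function(n = 150, qmin = 0.004, qmax = 0.2)
  seq(qmin, qmax, length.out = n)

# analytic sphere form factor, I(0) = 1
sphereCurve <- function(Rnm, q) {
  x <- q * Rnm * 10
  saxsCurve(q, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# uniform rod Rg (nm) for a cylinder
cylRg <- function(L, R) sqrt(L^2 / 12 + R^2 / 2)

# a small straight synthetic fibre image: width w px, horizontal, centred
straightFibreImage <- function(size = 256, w = 8, psf = 1, pixelSize = 0.5,
                               lengthPx = 200, angle = 0, contrast = 1,
                               noiseSd = 0, seed = 1) {
  cx <- size / 2; cy <- size / 2
  th <- angle * pi / 180
  half <- lengthPx / 2
  poly <- rbind(c(cx - half * cos(th), cy - half * sin(th)),
                c(cx + half * cos(th), cy + half * sin(th)))
  field <- renderFibreField(list(poly), w, size, psf)
  px <- -contrast * field
  if (noiseSd > 0)
    px <- px + withr::with_seed(seed, matrix(rnorm(size^2, 0, noiseSd),
                                             size, size))
  list(image = micrograph(px + 0.5, pixelSize, "DARK_RIDGES"), poly = poly)
}
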