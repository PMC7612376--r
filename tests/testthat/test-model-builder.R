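test_that("subunit bead rods have the calibrated bounding dimensions", {
  s22 <- subunitSpec("TWO_TWO")
  ext <- buildSubunitBeads(s22, useExtended = TRUE)
  z <- range(beadCoords(ext)[, 3])
  expect_equal(diff(z) + 2 * 0.25, 19, tolerance = 0.5 / 19)
  s44 <- subunitSpec("FOUR_FOUR")
  core <- buildSubunitBeads(s44)
  ranges <- apply(beadCoords(core), 2, function(v) diff(range(v)) + 0.5)
  expect_equal(ranges, c(4, 2, 14), tolerance = 0.05)
  expect_equal(s44@width, 2 * s22@width)
  # degenerate single-column grid
  tiny <- subunitSpec("TWO_TWO", coreLength = 1.5, extendedLength = 1.5,
                      width = 2, thickness = 2)
  one <- buildSubunitBeads(tiny, beadRadius = 1)
  expect_equal(nrow(beadCoords(one)), 1L)
  expect_error(buildSubunitBeads(s22, beadRadius = 3), "half")
})

test_that("fibre bead models reach the predicted discrete lengths", {
  for (kind in c("TWO_TWO", "FOUR_FOUR")) for (n in 1:4) {
    spec <- fibreModelSpec(subunitSpec(kind), n)
    m <- buildFibreBeads(spec)
    expect_lte(abs(modelDmax(m) - predictFibreLength(n)), 2 * 0.25)
    expect_equal(round(modelDmax(m)), predictFibreLength(n))
  }
  # n = 1 matches a 20-nm subunit rod
  m1 <- buildFibreBeads(fibreModelSpec(subunitSpec("FOUR_FOUR"), 1))
  s20 <- subunitSpec("FOUR_FOUR", coreLength = 20, extendedLength = 20)
  expect_equal(sort(beadCoords(m1)[, 3]),
               sort(beadCoords(buildSubunitBeads(s20))[, 3]))
})

test_that("overlap junctions are merged, not double-weighted", {
  m2 <- buildFibreBeads(fibreModelSpec(subunitSpec("TWO_TWO"), 2))
  key <- apply(round(beadCoords(m2), 6), 1, paste, collapse = "/")
  expect_false(any(duplicated(key)))
  expect_true(all(beadWeights(m2) == 1))
})

test_that("lateral copies widen the cross-section but not the length", {
  for (k in 2:3) {
    base <- buildFibreBeads(fibreModelSpec(subunitSpec("FOUR_FOUR"), 2))
    lat <- buildFibreBeads(fibreModelSpec(subunitSpec("FOUR_FOUR"), 2,
                                          lateralCopies = k))
    xspan <- function(m, j) diff(range(beadCoords(m)[, j]))
    expect_equal(xspan(lat, 1), xspan(base, 1) + (k - 1) * 5)
    expect_equal(xspan(lat, 3), xspan(base, 3))
  }
})

test_that("bead grids are translation invariant in pairwise distances", {
  m <- buildFibreBeads(fibreModelSpec(subunitSpec("TWO_TWO"), 2))
  shifted <- beadModel(sweep(beadCoords(m), 2, c(3.2, -1.4, 7.7), `+`),
                       radius = beadRadii(m), weight = beadWeights(m))
  expect_equal(sort(as.vector(dist(beadCoords(m)))),
               sort(as.vector(dist(beadCoords(shifted)))))
  expect_equal(modelDmax(m), modelDmax(shifted))
})

test_that("Dmax handles simple closed-form cases", {
  expect_equal(modelDmax(beadModel(rbind(c(0, 0, 0), c(0, 0, 10)),
                                   radius = 0.5)), 11)
  expect_equal(modelDmax(beadModel(matrix(0, 1, 3), radius = 0.7)), 1.4)
})

test_that("bead models round-trip through PDB dummy atoms", {
  m <- beadModel(rbind(c(0, 0, 0), c(1.234, -2.345, 10.5)),
                 radius = c(0.25, 0.5), weight = c(1, 2))
  f <- tempfile(fileext = ".pdb")
  writeBeadsPDB(m, f)
  back <- readBeadsPDB(f)
  expect_equal(nrow(beadCoords(back)), 2L)
  expect_equal(beadCoords(back), beadCoords(m), tolerance = 1e-3)
  expect_equal(beadRadii(back), beadRadii(m), tolerance = 1e-3)
  expect_equal(beadWeights(back), beadWeights(m), tolerance = 1e-2)
  expect_error(beadModel(matrix(0, 0, 3)), "at least one bead")
})

test_that("d-spacings match Table-1 cells and a reciprocal-vector oracle", {
  cell44 <- unitCell(42.67, 59.68, 156.49)
  expect_equal(dSpacing(cell44, 0, 0, 1), 156.49)
  expect_equal(dSpacing(cell44, 0, 1, 0), 59.68)
  expect_equal(dSpacing(cell44, 0, 1, 1),
               1 / sqrt(1 / 59.68^2 + 1 / 156.49^2), tolerance = 1e-9)
  expect_error(dSpacing(cell44, 0, 0, 0), "zero")

  # brute-force oracle: reciprocal basis from explicit direct-space vectors
  oracle <- function(cell, h, k, l) {
    d2r <- pi / 180
    ca <- cos(cell@alpha * d2r); cb <- cos(cell@beta * d2r)
    cg <- cos(cell@gamma * d2r); sg <- sin(cell@gamma * d2r)
    A <- c(cell@a, 0, 0)
    B <- c(cell@b * cg, cell@b * sg, 0)
    cx <- cell@c * cb
    cy <- cell@c * (ca - cb * cg) / sg
    C <- c(cx, cy, sqrt(cell@c^2 - cx^2 - cy^2))
    V <- sum(A * pracma::cross(B, C))
    As <- pracma::cross(B, C) / V
    Bs <- pracma::cross(C, A) / V
    Cs <- pracma::cross(A, B) / V
    1 / sqrt(sum((h * As + k * Bs + l * Cs)^2))
  }
  # monoclinic 2:2 cell: c-axis reflection needs the beta correction
  cell22 <- unitCell(88.52, 24.19, 88.48, beta = 115.737,
                     lattice = "P21")
  expect_equal(dSpacing(cell22, 0, 0, 1), oracle(cell22, 0, 0, 1))
  expect_lt(dSpacing(cell22, 0, 0, 1), 88.48)  # not the orthorhombic shortcut
  withr::with_seed(42, {
    for (i in 1:100) {
      cell <- unitCell(runif(1, 20, 200), runif(1, 20, 200),
                       runif(1, 20, 200), runif(1, 60, 120),
                       runif(1, 60, 120), runif(1, 60, 120))
      hkl <- sample(-4:4, 3, replace = TRUE)
      if (all(hkl == 0)) hkl <- c(1, 0, 0)
      expect_equal(dSpacing(cell, hkl[1], hkl[2], hkl[3]),
                   oracle(cell, hkl[1], hkl[2], hkl[3]), tolerance = 1e-9)
    }
  })
})

test_that("supercoil projection and lattice repeats are reported correctly", {
  expect_equal(kmefMeridional(5.4, 0), 5.4)
  expect_equal(kmefMeridional(5.4, 60), 2.7)
  expect_equal(kmefMeridional(5.4, 19.1), 5.4 * cos(19.1 * pi / 180))
  expect_equal(round(kmefMeridional(5.4, 19.1), 1), 5.1)
  expect_error(kmefMeridional(5.4, 90), "tilt")

  rep44 <- latticeRepeats(unitCell(42.67, 59.68, 156.49), "c")
  expect_equal(rep44$longitudinal, 15.649)
  expect_equal(sort(rep44$lateral), c(4.267, 5.968))
  cubic <- latticeRepeats(unitCell(100, 100, 100), "a")
  expect_equal(cubic$longitudinal, 10)
  expect_equal(cubic$lateral, c(10, 10))
})
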