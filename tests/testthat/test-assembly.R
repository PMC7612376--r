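test_that("discrete fibre lengths follow the initial-plus-increment rule", {
  expect_equal(predictFibreLength(1), 20)
  expect_equal(predictFibreLength(2), 35)
  expect_equal(predictFibreLength(3), 50)
  expect_equal(predictFibreLength(4), 65)
  expect_equal(enumerateAllowedLengths(nMax = 4), c(20, 35, 50, 65))
  expect_equal(enumerateAllowedLengths(nMax = 1), 20)
  # strictly increasing with exact step
  lens <- predictFibreLength(1:12)
  expect_true(all(diff(lens) == 15))
  # custom rule
  rule <- assemblyRule(initialLength = 22, increment = 15)
  expect_equal(predictFibreLength(3, rule), 52)
  expect_error(predictFibreLength(0), "positive integer")
  expect_error(enumerateAllowedLengths(nMax = 0), "positive integer")
  expect_error(assemblyRule(increment = 0), "positive")
  expect_error(assemblyRule(initialLength = 10, increment = 15,
                            latticeTranslation = 150), "exceed")
})

test_that("width classification uses non-overlapping left-closed intervals", {
  expect_equal(classifyFibreWidth(2.3), "2:2-fibre")
  expect_equal(classifyFibreWidth(3.6), "4:4-fibre")
  expect_equal(classifyFibreWidth(9.6), "10-nm fibre")
  expect_equal(classifyFibreWidth(25), "bundled fibre")
  expect_equal(classifyFibreWidth(100), "UNASSIGNED")
  expect_equal(classifyFibreWidth(c(1, 3, 7, 20)),
               c("2:2-fibre", "4:4-fibre", "10-nm fibre", "bundled fibre"))
  expect_error(classifyFibreWidth(-1), "positive")
  expect_error(widthTaxonomy(lower = c(0, 2, 7, 20),
                             upper = c(3, 7, 20, 40)), "overlap")
})

test_that("SC mass model reproduces the printed per-micron and total masses", {
  expect_equal(signif(scMassPerMicron(massModel(solventFraction = 0.8)), 2),
               1.6)
  expect_equal(signif(scMassPerMicron(massModel(solventFraction = 0.2)), 2),
               6.4)
  expect_equal(scMassPerMicron(massModel(solventFraction = 1)), 0)
  expect_equal(signif(scTotalMass(massModel(solventFraction = 0.2), 24), 3),
               154)
  expect_equal(signif(scTotalMass(massModel(solventFraction = 0.8), 4), 2),
               6.4)
  expect_error(scTotalMass(massModel(), -1), "positive")
})

test_that("mass model is linear in dry fraction and density", {
  base <- scMassPerMicron(massModel(solventFraction = 0.5))
  for (sf in seq(0, 1, by = 0.25)) {
    expect_equal(scMassPerMicron(massModel(solventFraction = sf)),
                 base * (1 - sf) / 0.5)
  }
  m2 <- massModel(solventFraction = 0.5, proteinDensity = 2.66)
  expect_equal(scMassPerMicron(m2), 2 * base)
  # monotone decreasing in solvent fraction
  vals <- vapply(seq(0, 1, by = 0.1),
                 function(sf) scMassPerMicron(massModel(solventFraction = sf)),
                 numeric(1))
  expect_true(all(diff(vals) < 0))
  # 24 um vs 4 um ratio is exactly 6 for any solvent fraction
  expect_equal(scTotalMass(massModel(), 24) / scTotalMass(massModel(), 4), 6)
})

test_that("heptad register maps congruent indices to identical letters", {
  # exhaustive against a brute-force table
  for (off in 0:6) {
    reg <- heptadRegister(1:70, offset = off)
    brute <- letters[((1:70 + off) %% 7) + 1]
    expect_identical(reg@letter, brute)
    expect_identical(reg@core, reg@letter %in% c("a", "d"))
  }
  # consecutive 1..7 always use all seven letters once
  expect_setequal(heptadRegister(1:7, offset = 3)@letter, letters[1:7])
  expect_error(heptadRegister(integer()), "non-empty")
  expect_error(heptadRegister(1:3, offset = 9), "0-6")
})

test_that("Ctip LFIL core and FFV surface residues separate by register", {
  lfil <- c(110, 114, 117, 121)
  ffv <- c(102, 109, 116)
  regLFIL <- heptadRegister(lfil)
  # all four on core positions, two congruence classes, gaps 4,3,4
  expect_true(all(regLFIL@core))
  expect_length(unique(lfil %% 7), 2L)
  expect_equal(diff(lfil), c(4, 3, 4))
  # FFV share a single non-core position at the same register
  regFFV <- heptadRegister(ffv, offset = regLFIL@registerOffset)
  expect_length(unique(regFFV@letter), 1L)
  expect_false(any(regFFV@core))
  expect_length(unique(ffv %% 7), 1L)
  # disjoint congruence classes
  expect_length(intersect(unique(lfil %% 7), unique(ffv %% 7)), 0L)
  # S2C hydrophobic core residues: two classes, gaps 4,3,4
  s2c <- c(149, 153, 156, 160)
  expect_length(unique(s2c %% 7), 2L)
  expect_equal(diff(s2c), c(4, 3, 4))
})

test_that("interface residue lookup is deterministic and validates indices", {
  reg <- heptadRegister(c(0, 7, 14, 5))
  tab <- classifyInterfaceResidues(reg, c(0, 7, 14))
  expect_length(unique(tab$letter), 1L)  # mod-7 congruent
  expect_equal(nrow(classifyInterfaceResidues(reg, 5)), 1L)
  expect_error(classifyInterfaceResidues(reg, 99), "not present")
})
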