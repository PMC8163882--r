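glyAlaSpectrum <- function() {
  # perfect spectrum of cyclic gly-ala: theoretical masses 57.02146, 71.03711
  masses <- c(57.02146, 71.03711)
  Spectrum("ga", sum(masses) + NRPlinker:::PROTON_MASS, 1L,
           masses + NRPlinker:::PROTON_MASS, c(1, 1))
}

test_that("exhaustive p-values are exact fractions on tiny spaces", {
  sp <- glyAlaSpectrum()
  # of the four {gly,ala}^2 cyclic dipeptides, gly-ala and ala-gly score 2
  expect_equal(pvalueExhaustive(sp, 2L, c("gly", "ala"), 2L,
                                topology = "cyclic", massTable = MASS_TABLE),
               0.5)
  expect_equal(pvalueExhaustive(sp, 2L, c("gly", "ala"), 0L,
                                topology = "cyclic", massTable = MASS_TABLE), 1)
  expect_error(pvalueExhaustive(sp, 20L, standardResiduesForTest(), 1L),
               "too large")
  set.seed(111)
  for (rep in 1:5) {
    spec <- fixtureSpec(rep, noisePeaks = 10L, peakDropout = 0.3)
    fx <- makeBgc(spec)
    st <- generateBackbones(fx$core, massTable = MASS_TABLE)[[2L]]
    spx <- simulateSpectrum(st, spec)
    p <- pvalueExhaustive(spx, 4L, c("gly", "ala", "val", "leu"),
                          sample(0:10, 1L), massTable = MASS_TABLE)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("splitting estimates are reproducible and bounded", {
  sp <- glyAlaSpectrum()
  a <- pvalueMcmc(sp, 4L, c("gly", "ala", "val"), 2L, nSim = 200L, seed = 5L,
                  massTable = MASS_TABLE)
  b <- pvalueMcmc(sp, 4L, c("gly", "ala", "val"), 2L, nSim = 200L, seed = 5L,
                  massTable = MASS_TABLE)
  expect_identical(a, b)
  expect_true(a$p_value > 0 && a$p_value <= 1)
  expect_equal(a$p_value, prod(a$levels$fraction))
  zero <- pvalueMcmc(sp, 4L, c("gly", "ala"), 0L, nSim = 200L, seed = 1L,
                     massTable = MASS_TABLE)
  expect_identical(zero$p_value, 1)
})

test_that("splitting tracks the exhaustive estimate on a small space", {
  spec <- fixtureSpec(5, nOrfs = 2L, modulesPerOrf = 3L)
  fx <- makeBgc(spec)
  st <- generateBackbones(fx$core, massTable = MASS_TABLE)[[2L]]
  sp <- simulateSpectrum(st, spec)
  alpha <- unique(c(fx$core, "gly"))
  obs <- spcScore(st, sp) - 8L   # a moderately rare tail, p ~ 1e-3..1e-5
  pe <- pvalueExhaustive(sp, 6L, alpha, obs, massTable = MASS_TABLE)
  ratios <- vapply(1:8, function(s)
    pvalueMcmc(sp, 6L, alpha, obs, nSim = 2000L, seed = s,
               massTable = MASS_TABLE)$p_value / pe, numeric(1))
  expect_true(mean(ratios >= 1 / 3 & ratios <= 3) >= 0.9)
})

test_that("E-values scale p-values by the search space", {
  expect_equal(eValue(1e-20, 1000, 100), 1e-15)
  expect_identical(eValue(0.25, 1, 1), 0.25)
  expect_true(eValue(1e-5, 10, 10) >= 1e-5)
  expect_error(eValue(0.1, 0, 5))
})

test_that("significance filtering applies the p-value threshold exactly", {
  psms <- data.frame(spectrumId = sprintf("s%d", 1:4),
                     score = c(30L, 25L, 20L, 10L),
                     pValue = c(1e-16, 1e-14, 1e-20, NA))
  got <- filterSignificant(psms)
  expect_setequal(got$spectrumId, c("s1", "s3"))
  expect_identical(filterSignificant(got), got)          # idempotent
  expect_identical(nrow(filterSignificant(psms[0, ])), 0L)
})

test_that("decoy FDR control drops low-scoring targets", {
  psms <- data.frame(spectrumId = sprintf("t%d", 1:6),
                     score = c(40L, 38L, 30L, 12L, 11L, 10L),
                     pValue = rep(1e-30, 6))
  decoys <- data.frame(score = c(12L, 11L, 10L, 9L))
  got <- filterSignificant(psms, decoyPsms = decoys, fdrPercent = 1)
  expect_setequal(got$spectrumId, c("t1", "t2", "t3"))
  loose <- filterSignificant(psms, decoyPsms = decoys, fdrPercent = 100)
  expect_identical(nrow(loose), 6L)
})

test_that("decoy structures shuffle residues but keep topology and mass", {
  st <- generateBackbones(c("gly", "ala", "val", "leu", "phe"),
                          hasP450 = TRUE, MASS_TABLE)[[5L]]
  dec <- makeDecoyStructures(list(st), seed = 3L)[[1L]]
  expect_identical(dec@topology, st@topology)
  expect_identical(dec@chord, st@chord)
  expect_setequal(dec@residues, st@residues)
  expect_equal(structureMass(dec), structureMass(st), tolerance = 1e-9)
})
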