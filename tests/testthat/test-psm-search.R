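perfectPair <- function(seed, n = 6L, topology = 2L, ...) {
  spec <- fixtureSpec(seed, nOrfs = 2L, modulesPerOrf = n %/% 2L, ...)
  fx <- makeBgc(spec)
  st <- generateBackbones(fx$core, massTable = MASS_TABLE)[[topology]]
  list(structure = st, spectrum = simulateSpectrum(st, spec), spec = spec)
}

test_that("shared-peak counting matches the worked tolerance example", {
  peaks <- sort(c(101.01728, 251.0, 300.99))
  expect_identical(NRPlinker:::matchedPeakCount(c(100, 200, 300), peaks, 0.02), 2L)
  expect_identical(NRPlinker:::matchedPeakCount(c(100, 200, 300), numeric(0), 0.02), 0L)
  # duplicate theoretical masses count once
  expect_identical(NRPlinker:::matchedPeakCount(c(100, 100), peaks, 0.02), 1L)
})

test_that("a perfect spectrum scores every distinct theoretical peak", {
  for (seed in 1:5) {
    pp <- perfectPair(seed)
    expect_identical(spcScore(pp$structure, pp$spectrum),
                     distinctMassCount(theoreticalSpectrum(pp$structure)$mass))
  }
  empty <- Spectrum("e", 500, 1L, numeric(0), numeric(0))
  pp <- perfectPair(9)
  expect_identical(spcScore(pp$structure, empty), 0L)
})

test_that("scores ignore peak order and duplicated peaks", {
  pp <- perfectPair(13)
  sp <- pp$spectrum
  perm <- sample(nrow(sp@peaks))
  sp2 <- Spectrum(sp@id, sp@precursorMz, sp@charge,
                  c(sp@peaks[perm, 1L], sp@peaks[, 1L]),
                  c(sp@peaks[perm, 2L], sp@peaks[, 2L]))
  expect_identical(spcScore(pp$structure, sp2), spcScore(pp$structure, sp))
})

test_that("standard matching gates on the precursor tolerance", {
  pp <- perfectPair(17)
  psm <- standardMatch(pp$structure, pp$spectrum)
  expect_identical(psm$score, spcScore(pp$structure, pp$spectrum))
  expect_true(is.na(psm$variantPosition))
  off <- pp$spectrum
  off@precursorMz <- off@precursorMz + 0.05
  expect_null(standardMatch(pp$structure, off))
})

test_that("variant search recovers a planted modification", {
  spec <- fixtureSpec(23, nOrfs = 2L, modulesPerOrf = 3L,
                      pamPosition = 2L, pamDelta = 99.06841)
  fx <- makeBgc(spec)
  st <- generateBackbones(fx$core, massTable = MASS_TABLE)[[2L]]
  sp <- simulateSpectrum(st, spec)
  psm <- variantSearch(st, sp)
  expect_identical(psm$variantPosition, 2L)
  expect_equal(psm$variantDelta, 99.06841, tolerance = 1e-4)
})

test_that("variant search with zero offset reduces to the standard match", {
  for (seed in 1:8) {
    pp <- perfectPair(seed * 3L)
    vs <- variantSearch(pp$structure, pp$spectrum)
    sm <- standardMatch(pp$structure, pp$spectrum)
    expect_identical(vs$score, sm$score)
  }
})

test_that("inadmissible offsets return no match", {
  pp <- perfectPair(29)
  sp <- pp$spectrum
  # more mass removed than any single residue carries
  sp@precursorMz <- structureMass(pp$structure) - 200 + NRPlinker:::PROTON_MASS
  expect_null(variantSearch(pp$structure, sp, maxMod = 250))
  # offsets beyond MaxMass are rejected outright
  sp@precursorMz <- structureMass(pp$structure) + 200 + NRPlinker:::PROTON_MASS
  expect_null(variantSearch(pp$structure, sp, maxMod = 150))
})

test_that("the exact position scan agrees with an independent rescan", {
  set.seed(101)
  for (rep in 1:60) {
    core <- sample(standardResiduesForTest(), sample(4:7, 1L))
    st <- generateBackbones(core, massTable = MASS_TABLE)[[sample(1:2, 1L)]]
    spec <- fixtureSpec(rep, peakDropout = 0.2, noisePeaks = 5L)
    truePos <- sample(length(core), 1L)
    omega <- runif(1, -50, 120)
    if (st@masses[truePos] + omega < 0) omega <- abs(omega)
    stv <- NRPlinker:::variantStructure(st, truePos, omega)
    sp <- simulateSpectrum(stv, spec, seedOffset = rep)
    psm <- variantSearch(st, sp, maxMod = 150)
    if (abs(omega) > 150) { expect_null(psm); next }
    oracle <- independentVariantBest(st, sp, omega)
    expect_identical(psm$variantPosition, oracle$position)
    expect_identical(psm$score, oracle$score)
  }
})

test_that("one-vs-all search finds hits missing from one-vs-one", {
  specA <- fixtureSpec(31, nOrfs = 2L, modulesPerOrf = 3L)
  specB <- fixtureSpec(37, nOrfs = 2L, modulesPerOrf = 3L)
  fxA <- makeBgc(specA); fxB <- makeBgc(specB)
  dbA <- generateBackbones(fxA$core, massTable = MASS_TABLE, source = "genomeA")
  dbB <- generateBackbones(fxB$core, massTable = MASS_TABLE, source = "genomeB")
  stB <- dbB[[2L]]
  sp <- simulateSpectrum(stB, specB)
  alone <- searchDataset(list(sp), dbA, mode = "one_vs_one")
  expect_lt(max(c(alone$score, 0L)), spcScore(stB, sp))
  both <- searchDataset(list(sp), list(genomeA = dbA, genomeB = dbB),
                        mode = "one_vs_all")
  top <- both[which.max(both$score), ]
  expect_identical(top$source, "genomeB")
  expect_identical(top$score, spcScore(stB, sp))
})

test_that("dataset search keeps the best PSM per spectrum and source", {
  pp <- perfectPair(41)
  db <- generateBackbones(pp$structure@residues, hasP450 = TRUE,
                          massTable = MASS_TABLE, source = "g")
  got <- searchDataset(list(pp$spectrum), db, mode = "one_vs_one")
  expect_identical(nrow(got), 1L)
  expect_identical(got$score, spcScore(pp$structure, pp$spectrum))
})
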