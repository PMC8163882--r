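test_that("residue masses resolve case-insensitively and round-trip", {
  expect_equal(residueMass("gly", MASS_TABLE), 57.02146)
  expect_equal(residueMass("ALA", MASS_TABLE), 71.03711)
  expect_error(residueMass("xyz", MASS_TABLE), "xyz",
               class = "nrplinker_lookup_error")
  f <- tempfile(fileext = ".tsv")
  writeResidueMassTable(MASS_TABLE, f)
  expect_identical(residueMassTable(f), MASS_TABLE)
})

test_that("backbone generation emits linear, cyclic and chord structures", {
  plainResidues <- c("gly", "ala", "val", "leu", "phe")
  noP450 <- generateBackbones(plainResidues, hasP450 = FALSE, MASS_TABLE)
  expect_length(noP450, 2L)
  expect_setequal(vapply(noP450, function(s) s@topology, character(1)),
                  c("linear", "cyclic"))
  withP450 <- generateBackbones(plainResidues, hasP450 = TRUE, MASS_TABLE)
  expect_length(withP450, 8L)
  chords <- Filter(function(s) s@topology == "branch_cyclic", withP450)
  expect_setequal(vapply(chords, function(s) paste(s@chord, collapse = "-"),
                         character(1)),
                  c("1-3", "1-4", "1-5", "2-4", "2-5", "3-5"))
})

test_that("linear and cyclic masses differ by one water", {
  st <- generateBackbones(c("gly", "ala", "val"), massTable = MASS_TABLE)
  expect_equal(structureMass(st[[2L]]), 227.12698, tolerance = 1e-9)
  expect_equal(structureMass(st[[1L]]), 245.13754, tolerance = 1e-9)
  set.seed(51)
  for (rep in 1:20) {
    core <- sample(standardResiduesForTest(), sample(3:10, 1L))
    st <- generateBackbones(core, massTable = MASS_TABLE)
    expect_equal(structureMass(st[[1L]]) - structureMass(st[[2L]]),
                 18.01056, tolerance = 1e-6)
  }
})

test_that("optional methylations expand to the power set of flagged positions", {
  st <- generateBackbones(c("gly", "ala", "val"), massTable = MASS_TABLE)[[2L]]
  none <- mkLine(c(gly = 100), c(ala = 100), c(val = 100))
  expect_length(applyKnownModifications(st, none), 1L)
  one <- mkLine(c(gly = 100), c(ala = 100), c(val = 100),
                methylation = c(FALSE, TRUE, FALSE))
  got1 <- applyKnownModifications(st, one)
  expect_length(got1, 2L)
  expect_equal(structureMass(got1[[2L]]) - structureMass(got1[[1L]]),
               14.01565, tolerance = 1e-9)
  expect_identical(got1[[2L]]@modifications$position, 2L)
  two <- mkLine(c(gly = 100), c(ala = 100), c(val = 100),
                methylation = c(TRUE, FALSE, TRUE))
  got2 <- applyKnownModifications(st, two)
  expect_length(got2, 4L)
  masses <- sort(vapply(got2, structureMass, numeric(1)))
  expect_equal(diff(masses), c(14.01565, 0, 14.01565), tolerance = 1e-9)
})

test_that("structure mass is additive over residues, deltas and water", {
  set.seed(61)
  for (rep in 1:20) {
    core <- sample(standardResiduesForTest(), 5L)
    line <- do.call(mkLine, c(lapply(core, function(a) stats::setNames(100, a)),
                              list(methylation = runif(5) < 0.4)))
    for (st in generateBackbones(core, hasP450 = TRUE, MASS_TABLE)) {
      for (v in applyKnownModifications(st, line)) {
        expect_equal(structureMass(v),
                     sum(residueMass(core, MASS_TABLE)) +
                       sum(v@modifications$delta) + v@waterOffset,
                     tolerance = 1e-6)
      }
    }
  }
})

test_that("invalid chords are rejected by the class validity", {
  expect_error(generateBackbones(c("gly", "ala"), massTable = MASS_TABLE))
  expect_error(new("NrpStructure", id = "x", residues = c("gly", "ala", "val"),
                   masses = c(1, 2, 3), topology = "branch_cyclic",
                   chord = c(1L, 2L), waterOffset = 0,
                   modifications = data.frame(position = integer(0),
                                              delta = numeric(0),
                                              label = character(0)),
                   source = "", adenylationScore = NA_real_),
               "chord")
})
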