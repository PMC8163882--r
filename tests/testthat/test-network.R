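simFor <- function(core, seed, ...) {
  spec <- fixtureSpec(seed, ...)
  st <- generateBackbones(core, massTable = MASS_TABLE)[[2L]]
  simulateSpectrum(st, spec, id = sprintf("%s#%d", paste(core, collapse = ""),
                                          seed), seedOffset = seed)
}

test_that("modified cosine is 1 on identical and 0 on disjoint spectra", {
  sp <- simFor(c("gly", "ala", "val", "leu", "phe"), 1)
  expect_equal(modifiedCosine(sp, sp), 1, tolerance = 1e-9)
  a <- Spectrum("a", 400, 1L, c(100, 150, 200), c(1, 1, 1))
  b <- Spectrum("b", 400, 1L, c(120, 170, 220), c(1, 1, 1))
  expect_equal(modifiedCosine(a, b), 0)
})

test_that("spectra of singly modified peptides stay similar via the shift", {
  core <- c("gly", "ala", "val", "leu", "phe")
  plain <- simFor(core, 2)
  spec <- fixtureSpec(2, pamPosition = 3L, pamDelta = 14.01565)
  st <- generateBackbones(core, massTable = MASS_TABLE)[[2L]]
  shifted <- simulateSpectrum(st, spec, id = "shifted", seedOffset = 2)
  expect_gte(modifiedCosine(plain, shifted), 0.7)
})

test_that("clustering groups replicates and separates unrelated peptides", {
  sp <- simFor(c("gly", "ala", "val", "leu", "phe"), 3)
  copies <- lapply(1:5, function(i)
    Spectrum(sprintf("c%d", i), sp@precursorMz, 1L, sp@peaks[, 1L],
             sp@peaks[, 2L]))
  expect_identical(length(unique(clusterSpectra(copies))), 1L)
  other <- simFor(c("trp", "tyr", "his", "arg", "lys"), 3)
  expect_identical(length(unique(clusterSpectra(list(sp, other)))), 2L)
  # jittered replicates of three peptides resolve into three clusters
  cores <- list(c("gly", "ala", "val", "leu", "phe"),
                c("trp", "tyr", "his", "arg", "lys"),
                c("ser", "thr", "pro", "met", "asn"))
  reps <- unlist(lapply(seq_along(cores), function(ci)
    lapply(1:10, function(i)
      simFor(cores[[ci]], seed = ci * 100L + i, massJitterSd = 0.004,
             peakDropout = 0.1))), recursive = FALSE)
  cl <- clusterSpectra(reps)
  expect_identical(length(unique(cl)), 3L)
  expect_identical(unname(vapply(split(seq_along(reps), cl), length,
                                 integer(1))), rep(10L, 3L))
})

test_that("families are components whose report needs a strong PSM", {
  core <- c("gly", "ala", "val", "leu", "phe")
  series1 <- lapply(0:2, function(k) {
    spec <- fixtureSpec(7, pamPosition = if (k) 2L else NULL,
                        pamDelta = k * 14.01565)
    st <- generateBackbones(core, massTable = MASS_TABLE)[[2L]]
    simulateSpectrum(st, spec, id = sprintf("s1_%d", k), seedOffset = k)
  })
  core2 <- c("trp", "tyr", "his", "arg", "lys")
  series2 <- lapply(0:2, function(k) {
    spec <- fixtureSpec(8, pamPosition = if (k) 2L else NULL,
                        pamDelta = k * 14.01565)
    st <- generateBackbones(core2, massTable = MASS_TABLE)[[2L]]
    simulateSpectrum(st, spec, id = sprintf("s2_%d", k), seedOffset = k)
  })
  spectra <- c(series1, series2)
  cl <- clusterSpectra(spectra)
  psms <- data.frame(spectrumId = c("s1_0", "s2_0"),
                     pValue = c(1e-25, 1e-18))
  net <- buildNetwork(spectra, cl, psms = psms)
  expect_identical(length(unique(net@membership)), 2L)
  fam <- net@families
  expect_identical(nrow(fam), 2L)
  expect_identical(sum(fam$reported), 1L)  # 1e-18 family suppressed
  expect_true(fam$reported[which(fam$bestPvalue == 1e-25)])
})

test_that("network counts nest and ignore input order", {
  spectra <- c(lapply(1:3, function(i) simFor(c("gly", "ala", "val", "leu",
                                                "phe"), 300L + i)),
               lapply(1:3, function(i) simFor(c("trp", "tyr", "his", "arg",
                                                "lys"), 400L + i)))
  cl <- clusterSpectra(spectra)
  net <- buildNetwork(spectra, cl)
  expect_lte(length(unique(net@membership)), length(unique(cl)))
  expect_lte(length(unique(cl)), length(spectra))
  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  cl2 <- clusterSpectra(spectra[perm])
  net2 <- buildNetwork(spectra[perm], cl2)
  expect_identical(length(unique(cl2)), length(unique(cl)))
  expect_identical(nrow(net2@families), nrow(net@families))
})

test_that("networks export as edge TSV and GraphML", {
  spectra <- lapply(1:3, function(i) simFor(c("gly", "ala", "val", "leu",
                                              "phe"), 500L + i))
  net <- buildNetwork(spectra, clusterSpectra(spectra))
  ef <- tempfile(fileext = ".tsv"); gf <- tempfile(fileext = ".graphml")
  writeNetwork(net, ef, gf)
  expect_true(file.exists(ef))
  expect_true(any(grepl("graphml", readLines(gf, n = 3L), ignore.case = TRUE)))
})
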