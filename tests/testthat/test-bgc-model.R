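surugamideLikeJson <- function(path) {
  mods <- function(k) lapply(seq_len(k), function(i) list(
    predictions = list(list(aa = "val", stachelhaus = 90, svm_tier = "single"),
                       list(aa = "ile", stachelhaus = 70, svm_tier = "large_cluster")),
    methylation = FALSE, epimerization = FALSE))
  doc <- list(id = "sur_like", has_p450 = FALSE,
              orfs = list(list(id = "surA", modules = mods(4L)),
                          list(id = "surB", modules = mods(1L)),
                          list(id = "surC", modules = mods(1L)),
                          list(id = "surD", modules = mods(2L))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}

test_that("JSON BGC reading preserves ORF and module order", {
  f <- surugamideLikeJson(tempfile(fileext = ".json"))
  bgc <- readBgc(f, "json")
  expect_s4_class(bgc, "Bgc")
  expect_identical(vapply(bgc@orfs, function(o) o@id, character(1)),
                   c("surA", "surB", "surC", "surD"))
  expect_identical(aDomainCount(bgc), 8L)
  expect_identical(vapply(bgc@orfs, function(o) length(o@modules), integer(1)),
                   c(4L, 1L, 1L, 2L))
})

test_that("degenerate and malformed BGC files raise parse errors", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "empty", orfs = list(list(id = "o1", modules = list()))),
                       f, auto_unbox = TRUE)
  expect_error(readBgc(f, "json"), "no modules", class = "nrplinker_parse_error")
  writeLines("not json at all {", f)
  expect_error(readBgc(f, "json"), class = "nrplinker_parse_error")
  expect_error(readBgc(tempfile(), "json"), "not found",
               class = "nrplinker_parse_error")
  ftsv <- tempfile(fileext = ".tsv")
  writeLines(c("#bgc_id=x\thas_p450=0", "orf\taa", "o1\tval"), ftsv)
  expect_error(readBgc(ftsv, "tsv"), "missing column",
               class = "nrplinker_parse_error")
})

test_that("unknown residues are reported by name", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x", orfs = list(list(id = "o1", modules = list(
    list(predictions = list(list(aa = "notaresidue", stachelhaus = 90,
                                 svm_tier = "single"))))))),
    f, auto_unbox = TRUE)
  expect_error(readBgc(f, "json"), "notaresidue",
               class = "nrplinker_lookup_error")
})

test_that("fixture BGCs round-trip through JSON and TSV", {
  for (seed in 1:12) {
    fx <- makeBgc(fixtureSpec(seed, nOrfs = sample(1:3, 1L),
                              modulesPerOrf = sample(1:3, 1L)))
    for (fmt in c("json", "tsv")) {
      f <- tempfile(fileext = paste0(".", fmt))
      writeBgc(fx$bgc, f, fmt)
      back <- readBgc(f, fmt)
      expect_true(bgcEqual(fx$bgc, back), label = sprintf("seed %d %s", seed, fmt))
      # reading is idempotent through a second round trip
      f2 <- tempfile(fileext = paste0(".", fmt))
      writeBgc(back, f2, fmt)
      expect_identical(readLines(f), readLines(f2))
      unlink(c(f, f2))
    }
  }
})

test_that("predictor tables map domains to deduplicated prediction sets", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("domain\taa\tstachelhaus\tsvm_tier",
               "d1\tval\t100\tsingle",
               "d1\tile\t80\tlarge_cluster",
               "d1\tile\t60\tlarge_cluster",
               paste(sprintf("d%d", 2:8), "ala", 70, "small_cluster", sep = "\t")),
             f)
  got <- parsePredictorTable(f)
  expect_length(got, 8L)
  expect_identical(names(got)[1L], "d1")
  d1 <- got[["d1"]]
  expect_equal(d1$stachelhaus[d1$aa == "ile"], 80)  # higher kept
  expect_identical(nrow(d1), 2L)
  expect_identical(d1$aa[d1$aa == "val"], "val")
  writeLines(c("domain\taa", "d1\tval"), f)
  expect_error(parsePredictorTable(f), "missing column",
               class = "nrplinker_parse_error")
})

test_that("A-domain count filter is an inclusive boundary and idempotent", {
  mod <- NrpsModule("val", 100, "single")
  bgc2 <- Bgc("b2", list(Orf("o1", list(mod, mod))))
  bgc3 <- Bgc("b3", list(Orf("o1", list(mod, mod, mod))))
  bgc8 <- Bgc("b8", list(Orf("o1", rep(list(mod), 8L))))
  expect_null(filterBgc(bgc2))
  expect_identical(filterBgc(bgc3), bgc3)
  expect_identical(filterBgc(bgc8), bgc8)
  expect_identical(filterBgc(filterBgc(bgc3)), filterBgc(bgc3))
})
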