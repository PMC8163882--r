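#' Read tandem mass spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE and peak
#' lines. Spectra are returned in file order. A block without CHARGE defaults
#' to 1+ with a warning; a block that cannot be parsed is skipped with a
#' message naming its title.
#'
#' @param path MGF file path.
#' @return list of \linkS4class{Spectrum}.
#' @export
readMgf <- function(path) {
  if (!file.exists(path)) parseError("MGF file not found: %s", path)
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends))
    parseError("%s: unbalanced BEGIN IONS / END IONS", path)
  out <- vector("list", length(starts))
  kept <- logical(length(starts))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1L])
    if (is.na(title)) title <- sprintf("spectrum_%d", b)
    sp <- tryCatch({
      pepmass <- grep("^PEPMASS=", block, value = TRUE)
      if (!length(pepmass)) parseError("missing PEPMASS")
      mz0 <- as.numeric(strsplit(sub("^PEPMASS=", "", pepmass[1L]), "[ \t]+")[[1L]][1L])
      chargeLine <- grep("^CHARGE=", block, value = TRUE)
      if (length(chargeLine)) {
        charge <- as.integer(gsub("[^0-9]", "", chargeLine[1L]))
      } else {
        warning(sprintf("spectrum '%s': missing CHARGE, assuming 1+", title),
                call. = FALSE)
        charge <- 1L
      }
      peakLines <- block[!grepl("=", block, fixed = TRUE) & nzchar(block)]
      pk <- do.call(rbind, lapply(strsplit(trimws(peakLines), "[ \t]+"),
                                  function(x) as.numeric(x[1:2])))
      if (is.null(pk) || anyNA(pk) || anyNA(mz0) || is.na(charge))
        parseError("bad numeric field")
      Spectrum(title, mz0, charge, pk[, 1L], pk[, 2L])
    }, error = function(e) {
      message(sprintf("skipping unparseable spectrum '%s': %s", title,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(sp)) { out[[b]] <- sp; kept[b] <- TRUE }
  }
  out[kept]
}

#' Write spectra to an MGF file
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    # %.17g: full double precision, so write/read round-trips peak lists
    # exactly
    writeLines(c("BEGIN IONS",
                 sprintf("TITLE=%s", sp@id),
                 sprintf("PEPMASS=%.17g", sp@precursorMz),
                 sprintf("CHARGE=%d+", sp@charge),
                 sprintf("%.17g %.17g", sp@peaks[, 1L], sp@peaks[, 2L]),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Drop sparse spectra
#'
#' Spectra with fewer than \code{minPeaks} peaks carry too little
#' fragmentation information for a shared-peak-count score and are removed.
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param minPeaks minimum retained peak count (default 20).
#' @return filtered list.
#' @export
filterSpectra <- function(spectra, minPeaks = 20L) {
  Filter(function(sp) nrow(sp@peaks) >= minPeaks, spectra)
}
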