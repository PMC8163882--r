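# Count theoretical masses (deduplicated at 1e-5 Da) having at least one
# experimental peak within eps of the singly protonated mass. Peaks must be
# sorted by m/z. A theoretical peak is counted at most once; an experimental
# peak may serve several theoretical peaks (pure per-theoretical-peak count).
matchedPeakCount <- function(theo, peakMz, eps) {
  if (!length(theo) || !length(peakMz)) return(0L)
  u <- sort(theo)
  u <- u[c(TRUE, diff(u) > 1e-5)]
  target <- u + PROTON_MASS
  lo <- findInterval(target - eps, peakMz)
  hi <- findInterval(target + eps, peakMz)
  sum(hi > lo)
}

#' Shared-peak-count score of a structure against a spectrum
#'
#' The number of distinct theoretical peaks of the structure's peptide graph
#' that lie within \code{epsilon} Da of an experimental peak, after the
#' proton offset applied to theoretical (neutral) masses.
#'
#' @param structure an \linkS4class{NrpStructure}.
#' @param spectrum a \linkS4class{Spectrum}.
#' @param epsilon fragment tolerance in Da (default 0.02).
#' @return integer score.
#' @export
spcScore <- function(structure, spectrum, epsilon = 0.02) {
  matchedPeakCount(theoreticalSpectrum(structure)$mass,
                   spectrum@peaks[, 1L], epsilon)
}

psmRow <- function(structure, spectrum, score,
                   variantPosition = NA_integer_, variantDelta = 0,
                   pValue = NA_real_, eValue = NA_real_) {
  data.frame(spectrumId = spectrum@id, structureId = structure@id,
             source = structure@source,
             core = paste(structure@residues, collapse = "-"),
             topology = structure@topology,
             variantPosition = as.integer(variantPosition),
             variantDelta = variantDelta, score = as.integer(score),
             pValue = pValue, eValue = eValue, stringsAsFactors = FALSE)
}

# Variant(P, i, delta): same topology, residue i shifted by delta.
variantStructure <- function(structure, position, delta) {
  structure@masses[position] <- structure@masses[position] + delta
  structure@modifications <- rbind(
    structure@modifications,
    data.frame(position = position, delta = delta, label = "PAM"))
  structure@id <- sprintf("%s[%+.5f@%d]", structure@id, delta, position)
  structure
}

#' Standard (unmodified) peptide-spectrum match
#'
#' Scores the structure against the spectrum only when the neutral precursor
#' mass and the structure mass agree within \code{delta} Da.
#'
#' @inheritParams spcScore
#' @param delta precursor tolerance in Da (default 0.02).
#' @return one-row PSM data.frame, or \code{NULL} when the precursor gate
#'   fails.
#' @export
standardMatch <- function(structure, spectrum, delta = 0.02, epsilon = 0.02) {
  if (abs(precursorNeutralMass(spectrum) - structureMass(structure)) > delta)
    return(NULL)
  psmRow(structure, spectrum, spcScore(structure, spectrum, epsilon))
}

#' Blind modification-tolerant variant search
#'
#' Considers a single post-assembly modification of mass
#' \code{omega = Mass(S) - Mass(P)} placed on each residue in turn (exact
#' position scan, no indexing heuristics) and returns the best-scoring
#' variant match; ties break to the smallest position index. Positions where
#' the shifted residue mass would become negative are inadmissible.
#'
#' @inheritParams spcScore
#' @param maxMod largest modification mass considered, in Da (default 150).
#' @return one-row PSM data.frame with the variant position and mass offset,
#'   or \code{NULL} when \code{|omega| > maxMod} or no position is
#'   admissible.
#' @export
variantSearch <- function(structure, spectrum, maxMod = 150, epsilon = 0.02) {
  omega <- precursorNeutralMass(spectrum) - structureMass(structure)
  if (abs(omega) > maxMod) return(NULL)
  n <- length(structure@residues)
  best <- NULL
  for (i in seq_len(n)) {
    if (structure@masses[i] + omega < 0) next
    sc <- spcScore(variantStructure(structure, i, omega), spectrum, epsilon)
    if (is.null(best) || sc > best$score) best <- list(position = i, score = sc)
  }
  if (is.null(best)) return(NULL)
  psmRow(structure, spectrum, best$score,
         variantPosition = best$position, variantDelta = omega)
}

#' Search a spectral dataset against a structure database
#'
#' For every spectrum, retains the best PSM per structure source. In
#' \code{one_vs_one} mode the database comes from a single genomic dataset;
#' in \code{one_vs_all} mode, a named list of databases is unioned and each
#' PSM is tagged with its source collection. A spectrum whose precursor is
#' within \code{delta} of a structure mass is scored unmodified; otherwise
#' the modification-tolerant variant search applies up to \code{maxMod}.
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param structureDb list of \linkS4class{NrpStructure}
#'   (\code{one_vs_one}), or a named list of such lists (\code{one_vs_all}).
#' @param mode \code{"one_vs_one"} or \code{"one_vs_all"}.
#' @param delta,epsilon,maxMod tolerances in Da.
#' @return data.frame of PSMs ordered by spectrum id, then score descending.
#' @export
searchDataset <- function(spectra, structureDb,
                          mode = c("one_vs_one", "one_vs_all"),
                          delta = 0.02, epsilon = 0.02, maxMod = 150) {
  mode <- match.arg(mode)
  if (mode == "one_vs_all") {
    stopifnot(!is.null(names(structureDb)))
    structureDb <- unlist(lapply(names(structureDb), function(src)
      lapply(structureDb[[src]], function(st) { st@source <- src; st })),
      recursive = FALSE)
  }
  rows <- list()
  for (sp in spectra) {
    bySource <- list()
    for (st in structureDb) {
      omega <- precursorNeutralMass(sp) - structureMass(st)
      psm <- if (abs(omega) <= delta) standardMatch(st, sp, delta, epsilon)
             else variantSearch(st, sp, maxMod, epsilon)
      if (is.null(psm)) next
      src <- st@source
      if (is.null(bySource[[src]]) || psm$score > bySource[[src]]$score)
        bySource[[src]] <- psm
    }
    rows <- c(rows, unname(bySource))
  }
  if (!length(rows))
    return(psmRow(new("NrpStructure", id = "", residues = character(0),
                      masses = numeric(0), topology = "linear",
                      chord = integer(0), waterOffset = 0,
                      modifications = data.frame(position = integer(0),
                                                 delta = numeric(0),
                                                 label = character(0)),
                      source = "", adenylationScore = NA_real_),
                  Spectrum("", 0, 1L, numeric(0), numeric(0)), 0)[0, ])
  out <- do.call(rbind, rows)
  out[order(out$spectrumId, -out$score, out$structureId), , drop = FALSE]
}
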