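METHYL_MASS <- 14.01565

#' Generate backbone structures for a core NRP
#'
#' Every core yields one linear backbone (free termini, +18.01056 Da water
#' offset) and one head-to-tail cyclic backbone (offset 0). When the source
#' cluster carries a cytochrome P450 domain, branch-cyclic backbones are
#' additionally generated for every side-chain chord (i, j) with
#' j >= i + 2 (adjacent pairs would duplicate existing backbone bonds).
#'
#' @param residues character vector of residue names (length >= 3).
#' @param hasP450 logical; emit branch-cyclic backbones.
#' @param massTable residue mass table.
#' @param id identifier prefix for the emitted structures.
#' @param score adenylation score carried along for reporting.
#' @param source provenance tag (e.g. BGC / assembly-line id).
#' @return list of \linkS4class{NrpStructure}.
#' @export
generateBackbones <- function(residues, hasP450 = FALSE,
                              massTable = residueMassTable(),
                              id = paste(residues, collapse = "-"),
                              score = NA_real_, source = "") {
  residues <- tolower(residues)
  n <- length(residues)
  stopifnot(n >= 3L)
  masses <- residueMass(residues, massTable)
  mk <- function(suffix, topology, chord, offset)
    new("NrpStructure", id = paste0(id, suffix), residues = residues,
        masses = masses, topology = topology, chord = chord,
        waterOffset = offset,
        modifications = data.frame(position = integer(0), delta = numeric(0),
                                   label = character(0)),
        source = source, adenylationScore = as.numeric(score))
  out <- list(mk("/linear", "linear", integer(0), WATER_MASS),
              mk("/cyclic", "cyclic", integer(0), 0))
  if (hasP450) {
    for (i in seq_len(n - 2L)) for (j in (i + 2L):n)
      out <- c(out, list(mk(sprintf("/bcyc%d-%d", i, j), "branch_cyclic",
                            c(i, j), 0)))
  }
  out
}

#' Apply known enzymatic modifications
#'
#' For every methylation-flagged position of the assembly line, emits both
#' the unmodified and the +14.01565 Da (monoisotopic methyl) variant, i.e.
#' the power set over flagged positions. Epimerization changes
#' stereochemistry, not mass, and is carried only as metadata upstream.
#'
#' @param structure an \linkS4class{NrpStructure}.
#' @param line the source \linkS4class{AssemblyLine} carrying per-position
#'   methylation flags.
#' @return list of \linkS4class{NrpStructure} (the input first).
#' @export
applyKnownModifications <- function(structure, line) {
  flagged <- which(line@methylation)
  flagged <- flagged[flagged <= length(structure@residues)]
  out <- list(structure)
  for (pos in flagged) {
    out <- c(out, lapply(out, function(st) {
      st@masses[pos] <- st@masses[pos] + METHYL_MASS
      st@modifications <- rbind(st@modifications,
                                data.frame(position = pos, delta = METHYL_MASS,
                                           label = "methylation"))
      st@id <- sprintf("%s+me%d", st@id, pos)
      st
    }))
  }
  out
}

#' Export structures as a TSV table
#'
#' @param structures list of \linkS4class{NrpStructure}.
#' @param path output file; when \code{NULL} the data.frame is returned only.
#' @return data.frame with one row per structure (id, core, topology, chord,
#'   mass), invisibly when written.
#' @export
structureTable <- function(structures, path = NULL) {
  df <- data.frame(
    id = vapply(structures, function(s) s@id, character(1)),
    core = vapply(structures, function(s) paste(s@residues, collapse = "-"),
                  character(1)),
    topology = vapply(structures, function(s) s@topology, character(1)),
    chord = vapply(structures, function(s)
      if (length(s@chord)) sprintf("%d-%d", s@chord[1], s@chord[2]) else "",
      character(1)),
    mass = vapply(structures, structureMass, numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
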