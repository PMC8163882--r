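#' Residue monoisotopic mass table
#'
#' Loads a residue mass table mapping case-insensitive residue names to
#' monoisotopic residue (dehydrated) masses in Da. The shipped default covers
#' the standard 20 proteinogenic residues plus common nonproteinogenic NRP
#' residues (Abu, Orn, Dab, Bht, Apa, Hyv).
#'
#' @param path optional path to a TSV with columns \code{name} and
#'   \code{monoisotopic_mass_Da}; defaults to the table shipped with the
#'   package.
#' @return named numeric vector (names lowercase).
#' @export
residueMassTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "residue_masses.tsv", package = "NRPlinker",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "monoisotopic_mass_Da") %in% names(tab)))
    parseError("residue mass table '%s' must have columns name, monoisotopic_mass_Da", path)
  stats::setNames(as.numeric(tab$monoisotopic_mass_Da), tolower(tab$name))
}

#' Write a residue mass table
#'
#' @param table named numeric vector as returned by [residueMassTable()].
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeResidueMassTable <- function(table, path) {
  utils::write.table(
    data.frame(name = names(table), monoisotopic_mass_Da = unname(table)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monoisotopic mass of one residue
#'
#' @param name residue name (case-insensitive).
#' @param table mass table from [residueMassTable()].
#' @return residue mass in Da.
#' @export
#' @examples
#' residueMass("gly")  # 57.02146
residueMass <- function(name, table = residueMassTable()) {
  key <- tolower(name)
  bad <- setdiff(unique(key), names(table))
  if (length(bad))
    lookupError("unknown residue(s): %s", paste(bad, collapse = ", "))
  unname(table[key])
}

# Standard-20 residue multiset used as the default null alphabet for p-values.
standardResidues <- function() {
  c("gly", "ala", "ser", "pro", "val", "thr", "cys", "leu", "ile", "asn",
    "asp", "gln", "lys", "glu", "met", "his", "phe", "arg", "tyr", "trp")
}
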