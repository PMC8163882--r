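#' @import methods
NULL

SVM_TIERS <- c("single", "small_cluster", "large_cluster", "none")

#' NRPS module with adenylation-domain substrate predictions
#'
#' One NRPS elongation module. The adenylation (A-) domain substrate
#' predictions are tiered: a Stachelhaus-code percent identity (0-100) and an
#' SVM prediction tier (\code{single}, \code{small_cluster},
#' \code{large_cluster}, \code{none}). Domain-presence flags (methylation
#' PF08242, epimerization, C-starter) are annotations carried in the input,
#' not HMM detections.
#'
#' @slot predictions data.frame with columns \code{aa}, \code{stachelhaus},
#'   \code{svm_tier}.
#' @slot methylation,epimerization,cStarter logical flags.
#' @export
setClass("NrpsModule", representation(
  predictions = "data.frame",
  methylation = "logical",
  epimerization = "logical",
  cStarter = "logical"
))

setValidity("NrpsModule", function(object) {
  p <- object@predictions
  if (!all(c("aa", "stachelhaus", "svm_tier") %in% names(p)))
    return("predictions must have columns aa, stachelhaus, svm_tier")
  if (nrow(p) > 0) {
    if (any(p$stachelhaus < 0 | p$stachelhaus > 100))
      return("stachelhaus must be in [0, 100]")
    if (!all(p$svm_tier %in% SVM_TIERS))
      return(sprintf("unknown svm_tier: %s",
                     paste(setdiff(p$svm_tier, SVM_TIERS), collapse = ", ")))
  }
  TRUE
})

#' Constructor for \linkS4class{NrpsModule}
#'
#' @param aa character vector of predicted residue names (case-insensitive
#'   keys into the residue mass table).
#' @param stachelhaus integer vector, percent identity 0-100.
#' @param svm_tier character vector of SVM tiers.
#' @param methylation,epimerization,cStarter logical flags.
#' @return an \linkS4class{NrpsModule}.
#' @export
NrpsModule <- function(aa, stachelhaus, svm_tier,
                       methylation = FALSE, epimerization = FALSE,
                       cStarter = FALSE) {
  new("NrpsModule",
      predictions = data.frame(aa = tolower(as.character(aa)),
                               stachelhaus = as.numeric(stachelhaus),
                               svm_tier = as.character(svm_tier),
                               stringsAsFactors = FALSE),
      methylation = isTRUE(methylation),
      epimerization = isTRUE(epimerization),
      cStarter = isTRUE(cStarter))
}

#' Open reading frame of an NRPS subunit
#'
#' @slot id character identifier.
#' @slot modules list of \linkS4class{NrpsModule}, order preserved as given.
#' @export
setClass("Orf", representation(id = "character", modules = "list"))

setValidity("Orf", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id)) return("id must be a single non-empty string")
  if (!all(vapply(object@modules, is, logical(1), "NrpsModule")))
    return("modules must all be NrpsModule objects")
  TRUE
})

#' Constructor for \linkS4class{Orf}
#' @param id identifier string.
#' @param modules list of \linkS4class{NrpsModule}.
#' @return an \linkS4class{Orf}.
#' @export
Orf <- function(id, modules) new("Orf", id = as.character(id), modules = modules)

#' Biosynthetic gene cluster
#'
#' Ordered ORFs, each an ordered run of NRPS modules. \code{hasP450} marks the
#' presence of a cytochrome P450 domain anywhere in the cluster, which licenses
#' branch-cyclic backbone generation downstream.
#'
#' @slot id character identifier.
#' @slot orfs list of \linkS4class{Orf} (file order preserved).
#' @slot hasP450 logical.
#' @export
setClass("Bgc", representation(id = "character", orfs = "list", hasP450 = "logical"))

setValidity("Bgc", function(object) {
  if (!all(vapply(object@orfs, is, logical(1), "Orf")))
    return("orfs must all be Orf objects")
  if (sum(vapply(object@orfs, function(o) length(o@modules), integer(1))) < 1L)
    return("BGC must contain at least one A-domain")
  TRUE
})

#' Constructor for \linkS4class{Bgc}
#' @param id identifier string.
#' @param orfs list of \linkS4class{Orf}.
#' @param hasP450 logical; cytochrome P450 domain present in the cluster.
#' @return a \linkS4class{Bgc}.
#' @export
Bgc <- function(id, orfs, hasP450 = FALSE)
  new("Bgc", id = as.character(id), orfs = orfs, hasP450 = isTRUE(hasP450))

#' NRPS assembly line
#'
#' The ordered sequence of A-domain scored alphabets A_1..A_n that an
#' (optionally non-canonical) arrangement of NRPS subunits presents to the
#' downstream filtering stages. \code{multiplicities} records how many times
#' each source ORF appears (0 under ORF deletion, 2-3 under tandem
#' duplication).
#'
#' @slot bgcId source BGC identifier.
#' @slot orfIds character vector of source ORF ids (one per source ORF).
#' @slot multiplicities integer vector parallel to \code{orfIds}.
#' @slot alphabets list of data.frames (\code{aa}, \code{score}, \code{norm}),
#'   one per A-domain position.
#' @slot methylation,epimerization logical vectors, one flag per position.
#' @export
setClass("AssemblyLine", representation(
  bgcId = "character",
  orfIds = "character",
  multiplicities = "integer",
  alphabets = "list",
  methylation = "logical",
  epimerization = "logical"
))

setValidity("AssemblyLine", function(object) {
  n <- length(object@alphabets)
  if (length(object@orfIds) != length(object@multiplicities))
    return("orfIds and multiplicities must be parallel")
  if (any(object@multiplicities < 0L | object@multiplicities > 3L))
    return("ORF copy counts must be in 0..3")
  if (length(object@methylation) != n || length(object@epimerization) != n)
    return("per-position annotation length mismatch")
  for (a in object@alphabets) {
    if (!all(c("aa", "score", "norm") %in% names(a)) || nrow(a) == 0L)
      return("each alphabet needs >= 1 row with columns aa, score, norm")
    if (max(a$norm) != 100L || any(a$norm < 1L))
      return("normalized scores must lie in [1, 100] with max exactly 100")
  }
  TRUE
})

#' Number of A-domain positions in an assembly line
#' @param line an \linkS4class{AssemblyLine}.
#' @return integer.
#' @export
nPositions <- function(line) length(line@alphabets)

#' Scored alphabets of an assembly line
#' @param line an \linkS4class{AssemblyLine}.
#' @return list of data.frames with columns \code{aa}, \code{score}, \code{norm}.
#' @export
alphabets <- function(line) line@alphabets

#' Per-score core-NRP count table
#'
#' Row i+1, column s+1 holds the number of length-i prefix cores with
#' adenylation score exactly s; the last row is the full distribution whose
#' total equals the product of alphabet sizes. Counts are stored as doubles
#' (exact for counts below 2^53; genome-scale alphabets overflow 32-bit
#' integers).
#'
#' @slot counts numeric matrix, (n+1) x (100 n + 1).
#' @slot alphabetSizes integer vector |A_1|..|A_n|.
#' @export
setClass("ScoreCountTable", representation(counts = "matrix", alphabetSizes = "integer"))

setValidity("ScoreCountTable", function(object) {
  n <- length(object@alphabetSizes)
  if (nrow(object@counts) != n + 1L) return("counts must have n+1 rows")
  if (ncol(object@counts) != 100L * n + 1L) return("counts must span scores 0..100n")
  if (abs(sum(object@counts[n + 1L, ]) - prod(object@alphabetSizes)) > 0.5)
    return("final-row total must equal the product of alphabet sizes")
  TRUE
})

#' NRP structure as a peptide graph
#'
#' Residue nodes joined by generalized peptide bonds. Topologies: linear
#' (path, water offset +18.01056 Da for the free termini), cyclic
#' (head-to-tail cycle, offset 0) and branch-cyclic (path plus one side-chain
#' chord, offset 0). \code{modifications} lists applied known enzymatic
#' modifications as (position, delta, label).
#'
#' @slot id character identifier.
#' @slot residues character vector of residue names.
#' @slot masses numeric vector of residue masses (modification deltas already
#'   applied).
#' @slot topology one of \code{"linear"}, \code{"cyclic"},
#'   \code{"branch_cyclic"}.
#' @slot chord integer(2) chord endpoints for branch-cyclic, else integer(0).
#' @slot waterOffset numeric mass offset in Da.
#' @slot modifications data.frame (\code{position}, \code{delta},
#'   \code{label}).
#' @slot source character; free-form provenance tag (BGC / assembly line).
#' @slot adenylationScore numeric; score of the underlying core NRP.
#' @export
setClass("NrpStructure", representation(
  id = "character",
  residues = "character",
  masses = "numeric",
  topology = "character",
  chord = "integer",
  waterOffset = "numeric",
  modifications = "data.frame",
  source = "character",
  adenylationScore = "numeric"
))

setValidity("NrpStructure", function(object) {
  n <- length(object@residues)
  if (length(object@masses) != n) return("masses must parallel residues")
  if (!object@topology %in% c("linear", "cyclic", "branch_cyclic"))
    return("unknown topology")
  if (object@topology == "branch_cyclic") {
    ch <- object@chord
    if (length(ch) != 2L || ch[2L] < ch[1L] + 2L || ch[1L] < 1L || ch[2L] > n)
      return("branch-cyclic chord must be (i, j) with j >= i + 2 inside 1..n")
  } else if (length(object@chord) != 0L) {
    return("chord only allowed for branch_cyclic topology")
  }
  if (any(object@masses < 0)) return("residue masses must be nonnegative")
  TRUE
})

#' Total neutral mass of a structure
#'
#' Sum of residue masses (with applied modification deltas) plus the
#' topology's water offset.
#'
#' @param structure an \linkS4class{NrpStructure}.
#' @return mass in Da.
#' @export
structureMass <- function(structure) sum(structure@masses) + structure@waterOffset

#' Tandem mass spectrum
#'
#' @slot id character identifier (MGF TITLE or generated).
#' @slot precursorMz numeric precursor m/z in Da.
#' @slot charge integer charge state.
#' @slot peaks numeric matrix with columns \code{mz}, \code{intensity},
#'   sorted by m/z.
#' @export
setClass("Spectrum", representation(
  id = "character", precursorMz = "numeric", charge = "integer",
  peaks = "matrix"
))

setValidity("Spectrum", function(object) {
  pk <- object@peaks
  if (ncol(pk) != 2L) return("peaks must have columns mz, intensity")
  if (nrow(pk) > 1L && is.unsorted(pk[, 1L])) return("peaks must be sorted by m/z")
  if (object@charge < 1L) return("charge must be a positive integer")
  TRUE
})

#' Constructor for \linkS4class{Spectrum}
#'
#' @param id identifier.
#' @param precursorMz precursor m/z (Da).
#' @param charge positive integer charge state.
#' @param mz,intensity numeric peak vectors (re-sorted by m/z).
#' @return a \linkS4class{Spectrum}.
#' @export
Spectrum <- function(id, precursorMz, charge, mz, intensity) {
  o <- order(mz)
  new("Spectrum", id = as.character(id), precursorMz = as.numeric(precursorMz),
      charge = as.integer(charge),
      peaks = cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o]))
}

#' Neutral precursor mass of a spectrum
#' @param spectrum a \linkS4class{Spectrum}.
#' @return neutral mass in Da, \code{charge * (precursorMz - 1.00728)}.
#' @export
precursorNeutralMass <- function(spectrum)
  neutralMass(spectrum@precursorMz, spectrum@charge)

#' Spectral network of identified spectra
#'
#' @slot nodes data.frame of cluster representatives (one row per cluster).
#' @slot edges data.frame (\code{from}, \code{to}, \code{cosine},
#'   \code{shift}).
#' @slot membership integer vector: family (connected component) per node.
#' @slot families data.frame of family summaries (size, best p-value,
#'   reported flag).
#' @export
setClass("SpectralNetwork", representation(
  nodes = "data.frame", edges = "data.frame",
  membership = "integer", families = "data.frame"
))

## show methods ---------------------------------------------------------------

setMethod("show", "Bgc", function(object) {
  nm <- vapply(object@orfs, function(o) length(o@modules), integer(1))
  cat(sprintf("Bgc '%s': %d ORF(s), %d A-domain(s)%s\n", object@id,
              length(object@orfs), sum(nm),
              if (object@hasP450) ", P450 present" else ""))
  for (o in object@orfs)
    cat(sprintf("  %s: %d module(s)\n", o@id, length(o@modules)))
})

setMethod("show", "AssemblyLine", function(object) {
  pat <- paste(sprintf("%sx%d", object@orfIds, object@multiplicities), collapse = " ")
  cat(sprintf("AssemblyLine [%s] from '%s': %d position(s)\n",
              pat, object@bgcId, nPositions(object)))
})

setMethod("show", "ScoreCountTable", function(object) {
  n <- length(object@alphabetSizes)
  tot <- sum(object@counts[n + 1L, ])
  cat(sprintf("ScoreCountTable: %d position(s), %s core NRP(s), max score %d\n",
              n, format(tot, big.mark = ","), 100L * n))
})

setMethod("show", "NrpStructure", function(object) {
  cat(sprintf("NrpStructure '%s' (%s%s): %s | mass %.5f Da\n", object@id,
              object@topology,
              if (length(object@chord)) sprintf(" %d-%d", object@chord[1], object@chord[2]) else "",
              paste(object@residues, collapse = "-"), structureMass(object)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': precursor m/z %.5f (%d+), %d peak(s)\n",
              object@id, object@precursorMz, object@charge, nrow(object@peaks)))
})

setMethod("show", "SpectralNetwork", function(object) {
  cat(sprintf("SpectralNetwork: %d node(s), %d edge(s), %d family component(s)\n",
              nrow(object@nodes), nrow(object@edges),
              length(unique(object@membership))))
})
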