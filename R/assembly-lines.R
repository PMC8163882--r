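MIN_MODULES <- 3L
MAX_MODULES <- 20L

# Build one AssemblyLine from a BGC given per-ORF copy counts. Alphabets are
# shared (copied by reference semantics of R lists), never mutated.
buildLine <- function(bgc, multiplicities, alph = bgcAlphabets(bgc)) {
  stopifnot(length(multiplicities) == length(bgc@orfs))
  lineAlph <- list(); meth <- logical(0); epi <- logical(0)
  for (j in seq_along(bgc@orfs)) {
    for (rep in seq_len(multiplicities[j])) {
      mods <- bgc@orfs[[j]]@modules
      lineAlph <- c(lineAlph, alph[[j]])
      meth <- c(meth, vapply(mods, function(m) m@methylation, logical(1)))
      epi <- c(epi, vapply(mods, function(m) m@epimerization, logical(1)))
    }
  }
  new("AssemblyLine", bgcId = bgc@id,
      orfIds = vapply(bgc@orfs, function(o) o@id, character(1)),
      multiplicities = as.integer(multiplicities),
      alphabets = lineAlph, methylation = meth, epimerization = epi)
}

lineModuleCount <- function(bgc, multiplicities) {
  sum(vapply(bgc@orfs, function(o) length(o@modules), integer(1)) * multiplicities)
}

keepLineSizes <- function(bgc, multis, minModules, maxModules) {
  sizes <- vapply(multis, function(m) lineModuleCount(bgc, m), numeric(1))
  drop <- sizes < minModules | sizes > maxModules
  if (any(drop))
    message(sprintf("dropped %d assembly line(s) outside the %d-%d module bound",
                    sum(drop), minModules, maxModules))
  multis[!drop]
}

#' Assembly line from a normalized-score table
#'
#' Builds an \linkS4class{AssemblyLine} directly from a long-format table of
#' per-position normalized specificity scores, as published for worked
#' examples (columns \code{position}, \code{aa}, \code{normalized_score}).
#' Useful when the scored alphabets are themselves the input, bypassing the
#' Stachelhaus/SVM evidence combination.
#'
#' @param scores data.frame with columns \code{position} (1..n), \code{aa}
#'   and \code{normalized_score} (integers in [1, 100], max 100 per
#'   position).
#' @param bgcId identifier recorded as the source.
#' @return an \linkS4class{AssemblyLine} with no modification flags.
#' @export
assemblyLineFromScores <- function(scores, bgcId = "scored_input") {
  stopifnot(all(c("position", "aa", "normalized_score") %in% names(scores)))
  positions <- sort(unique(scores$position))
  stopifnot(identical(as.integer(positions), seq_along(positions)))
  alph <- lapply(positions, function(p) {
    sub <- scores[scores$position == p, , drop = FALSE]
    data.frame(aa = tolower(sub$aa), score = as.numeric(sub$normalized_score),
               norm = as.integer(sub$normalized_score),
               stringsAsFactors = FALSE)
  })
  n <- length(alph)
  new("AssemblyLine", bgcId = bgcId, orfIds = bgcId, multiplicities = 1L,
      alphabets = alph, methylation = rep(FALSE, n),
      epimerization = rep(FALSE, n))
}

#' Assembly lines by ORF deletion
#'
#' Generates the canonical assembly line plus every line obtained by deleting
#' up to \code{maxDeletions} whole NRPS subunits (ORFs) at any positions,
#' remaining ORF order preserved. Lines outside the module-count bounds are
#' dropped.
#'
#' @param bgc a \linkS4class{Bgc} accepted by [filterBgc()].
#' @param maxDeletions maximum number of deleted ORFs (default 2).
#' @param minModules,maxModules retained line size bounds (defaults 3 and 20).
#' @return list of \linkS4class{AssemblyLine}.
#' @export
generateOrfDel <- function(bgc, maxDeletions = 2L,
                           minModules = MIN_MODULES, maxModules = MAX_MODULES) {
  k <- length(bgc@orfs)
  multis <- list()
  for (d in 0:min(maxDeletions, k - 1L)) {
    for (del in if (d == 0L) list(integer(0)) else
                asplit(utils::combn(k, d), 2L)) {
      m <- rep(1L, k); m[del] <- 0L
      multis <- c(multis, list(m))
    }
  }
  multis <- keepLineSizes(bgc, multis, minModules, maxModules)
  alph <- bgcAlphabets(bgc)
  lapply(multis, function(m) buildLine(bgc, m, alph))
}

#' Assembly lines by tandem ORF duplication
#'
#' Generates the canonical assembly line plus lines in which exactly one
#' ORF's modules are repeated in tandem one or two extra times (the subunit
#' appearing two or three times), modeling iterative use of a single NRPS
#' subunit.
#'
#' @inheritParams generateOrfDel
#' @param maxExtraCopies maximum extra tandem copies of one ORF (default 2).
#' @return list of \linkS4class{AssemblyLine}.
#' @export
generateOrfDup <- function(bgc, maxExtraCopies = 2L,
                           minModules = MIN_MODULES, maxModules = MAX_MODULES) {
  k <- length(bgc@orfs)
  multis <- list(rep(1L, k))
  if (maxExtraCopies > 0L) {
    for (j in seq_len(k)) for (extra in seq_len(maxExtraCopies)) {
      m <- rep(1L, k); m[j] <- 1L + extra
      multis <- c(multis, list(m))
    }
  }
  multis <- keepLineSizes(bgc, multis, minModules, maxModules)
  alph <- bgcAlphabets(bgc)
  lapply(multis, function(m) buildLine(bgc, m, alph))
}

#' Enumerate assembly lines of a BGC
#'
#' Union of the requested generators, de-duplicated on the ORF multiplicity
#' pattern and ordered deterministically: descending module count, then the
#' multiplicity pattern lexicographically.
#'
#' @inheritParams generateOrfDel
#' @param mode one of \code{"canonical"}, \code{"orfdel"}, \code{"orfdup"},
#'   \code{"both"}.
#' @return list of \linkS4class{AssemblyLine}.
#' @export
enumerateAssemblyLines <- function(bgc,
                                   mode = c("canonical", "orfdel", "orfdup", "both"),
                                   minModules = MIN_MODULES,
                                   maxModules = MAX_MODULES) {
  mode <- match.arg(mode)
  lines <- list()
  if (mode == "canonical") {
    k <- length(bgc@orfs)
    if (lineModuleCount(bgc, rep(1L, k)) >= minModules &&
        lineModuleCount(bgc, rep(1L, k)) <= maxModules)
      lines <- list(buildLine(bgc, rep(1L, k)))
  }
  if (mode %in% c("orfdel", "both"))
    lines <- c(lines, generateOrfDel(bgc, minModules = minModules,
                                     maxModules = maxModules))
  if (mode %in% c("orfdup", "both"))
    lines <- c(lines, generateOrfDup(bgc, minModules = minModules,
                                     maxModules = maxModules))
  pat <- vapply(lines, function(l) paste(l@multiplicities, collapse = ","),
                character(1))
  lines <- lines[!duplicated(pat)]
  sizes <- vapply(lines, nPositions, integer(1))
  pat <- pat[!duplicated(pat)]
  lines[order(-sizes, pat)]
}
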