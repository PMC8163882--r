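# Batch shared-peak-count scoring of many peptides with a common topology.
# massMatrix is N x n residue masses; fragment node sets depend only on the
# topology, so fragment masses come from one matrix product. Each row is then
# scored with the same dedup-and-match rule as spcScore().
batchSpcScores <- function(massMatrix, topology, chord, peakMz, epsilon) {
  n <- ncol(massMatrix)
  frags <- fragmentNodeSets(topology, n, chord)
  W <- vapply(frags, function(f) {
    v <- numeric(n); v[f$nodes] <- 1; v
  }, numeric(n))
  off <- vapply(frags, function(f) fragmentWaterOffset(topology, f$nodes, n),
                numeric(1))
  fm <- massMatrix %*% W
  fm <- sweep(fm, 2L, off, "+")
  # vectorized peak matching over the whole matrix; per-row work reduces to
  # deduplicating the (few) matched masses, same rule as matchedPeakCount()
  target <- as.vector(fm) + PROTON_MASS
  matched <- matrix(findInterval(target + epsilon, peakMz) >
                      findInterval(target - epsilon, peakMz), nrow(fm))
  idx <- which(matched)
  if (!length(idx)) return(integer(nrow(fm)))
  rows <- (idx - 1L) %% nrow(fm) + 1L
  vals <- fm[idx]
  o <- order(rows, vals)
  rows <- rows[o]; vals <- vals[o]
  # a matched mass starts a new distinct value at a row boundary or a >1e-5 gap
  newVal <- c(TRUE, rows[-1L] != rows[-length(rows)] |
                      diff(vals) > 1e-5)
  tabulate(rows[newVal], nbins = nrow(fm))
}

#' Exact PSM p-value by exhaustive enumeration
#'
#' Fraction of all |alphabet|^n peptides of the given topology whose
#' shared-peak-count score against the spectrum reaches the observed score.
#' Feasible only for small search spaces; serves as the ground-truth
#' counterpart of [pvalueMcmc()].
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param n peptide length.
#' @param alphabet character vector of residue names the random peptides draw
#'   from.
#' @param observedScore the PSM score whose tail probability is wanted.
#' @param topology backbone topology of the random peptides.
#' @param chord chord endpoints when \code{topology = "branch_cyclic"}.
#' @param epsilon fragment tolerance (Da).
#' @param massTable residue mass table.
#' @return exact p-value in (0, 1].
#' @export
pvalueExhaustive <- function(spectrum, n, alphabet, observedScore,
                             topology = "cyclic", chord = integer(0),
                             epsilon = 0.02, massTable = residueMassTable()) {
  k <- length(alphabet)
  total <- k^n
  if (total > 1e6) stop(sprintf("search space %g too large for enumeration", total))
  if (observedScore <= 0) return(1)
  amass <- residueMass(alphabet, massTable)
  peakMz <- spectrum@peaks[, 1L]
  hits <- 0; blockSize <- 65536L
  idx <- 0
  while (idx < total) {
    take <- min(blockSize, total - idx)
    codes <- idx + seq_len(take) - 1
    M <- matrix(0, take, n)
    rest <- codes
    for (j in seq_len(n)) {
      M[, j] <- amass[rest %% k + 1]
      rest <- rest %/% k
    }
    sc <- batchSpcScores(M, topology, chord, peakMz, epsilon)
    hits <- hits + sum(sc >= observedScore)
    idx <- idx + take
  }
  max(hits, 1) / total
}

#' PSM p-value by multilevel-splitting Monte Carlo
#'
#' Estimates the probability that a random peptide of the same length and
#' topology scores at least as high as the observed match. A population of
#' uniform random peptides is pushed toward high scores through adaptively
#' raised score levels: at each level the surviving fraction is recorded, the
#' population restarts from survivors, and a Markov kernel of single-position
#' residue substitutions (rejected when the score drops below the level)
#' diversifies it. The p-value is the product of the conditional survival
#' fractions, a standard rare-event splitting estimator.
#'
#' @inheritParams pvalueExhaustive
#' @param nSim population size per level (default 10000).
#' @param seed integer seed; the estimate is reproducible given the seed.
#' @param quantile survival fraction targeted when raising a level
#'   (default 0.1).
#' @param moveSteps substitution sweeps applied to the restarted population
#'   per level (default 3).
#' @param maxLevels safety bound on the number of levels.
#' @return list with elements \code{p_value}, \code{n_simulations},
#'   \code{levels} (data.frame of threshold and conditional fraction) and
#'   \code{seed}.
#' @export
pvalueMcmc <- function(spectrum, n, alphabet, observedScore,
                       topology = "cyclic", chord = integer(0),
                       nSim = 10000L, seed = 1L, epsilon = 0.02,
                       quantile = 0.1, moveSteps = 3L, maxLevels = 60L,
                       massTable = residueMassTable()) {
  stopifnot(nSim >= 100L)
  if (observedScore <= 0)
    return(list(p_value = 1, n_simulations = nSim,
                levels = data.frame(threshold = numeric(0), fraction = numeric(0)),
                seed = seed))
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  amass <- residueMass(alphabet, massTable)
  k <- length(amass)
  peakMz <- spectrum@peaks[, 1L]
  M <- matrix(amass[sample.int(k, nSim * n, replace = TRUE)], nSim, n)
  scores <- batchSpcScores(M, topology, chord, peakMz, epsilon)
  fractions <- numeric(0); thresholds <- numeric(0)
  threshold <- -Inf
  for (lev in seq_len(maxLevels)) {
    cand <- sort(scores)[ceiling((1 - quantile) * nSim)]
    if (cand <= threshold) cand <- threshold + 1L
    if (cand >= observedScore) {
      frac <- mean(scores >= observedScore)
      if (frac == 0) frac <- 1 / (nSim + 1)   # conservative floor
      fractions <- c(fractions, frac)
      thresholds <- c(thresholds, observedScore)
      break
    }
    frac <- mean(scores >= cand)
    if (frac == 0) {                          # dead level: no survivors
      fractions <- c(fractions, 1 / (nSim + 1))
      thresholds <- c(thresholds, cand)
      break
    }
    fractions <- c(fractions, frac)
    thresholds <- c(thresholds, cand)
    threshold <- cand
    keep <- which(scores >= threshold)
    resample <- keep[sample.int(length(keep), nSim, replace = TRUE)]
    M <- M[resample, , drop = FALSE]
    scores <- scores[resample]
    for (step in seq_len(moveSteps)) {
      pos <- sample.int(n, nSim, replace = TRUE)
      res <- amass[sample.int(k, nSim, replace = TRUE)]
      M2 <- M
      M2[cbind(seq_len(nSim), pos)] <- res
      s2 <- batchSpcScores(M2, topology, chord, peakMz, epsilon)
      accept <- s2 >= threshold
      M[accept, ] <- M2[accept, , drop = FALSE]
      scores[accept] <- s2[accept]
    }
  }
  list(p_value = prod(fractions), n_simulations = nSim,
       levels = data.frame(threshold = thresholds, fraction = fractions),
       seed = seed)
}

#' E-value of a PSM
#'
#' Bonferroni-style expectation: the p-value multiplied by the numbers of
#' spectra and candidate structures searched.
#'
#' @param p p-value.
#' @param nSpectra,nStructures positive search-space sizes.
#' @return E-value.
#' @export
eValue <- function(p, nSpectra, nStructures) {
  stopifnot(nSpectra > 0, nStructures > 0)
  p * nSpectra * nStructures
}

#' Decoy structures by residue shuffling
#'
#' Permutes each structure's residue order while preserving topology, chord
#' and applied modification set, yielding a decoy database for target-decoy
#' FDR estimation.
#'
#' @param structures list of \linkS4class{NrpStructure}.
#' @param seed integer seed.
#' @return list of decoy \linkS4class{NrpStructure}.
#' @export
makeDecoyStructures <- function(structures, seed = 1L) {
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  lapply(structures, function(st) {
    perm <- sample.int(length(st@residues))
    st@residues <- st@residues[perm]
    st@masses <- st@masses[perm]
    st@id <- paste0("decoy:", st@id)
    st@source <- paste0("decoy:", st@source)
    st
  })
}

#' Filter PSMs by statistical significance
#'
#' Retains PSMs with p-value at most \code{pThreshold}. When a decoy PSM
#' table is supplied, additionally applies a score cutoff at which the
#' target-decoy false discovery rate is at most \code{fdrPercent}.
#'
#' @param psms PSM data.frame with a \code{pValue} column.
#' @param pThreshold p-value threshold (default 1e-15).
#' @param decoyPsms optional PSM data.frame from a decoy-database search.
#' @param fdrPercent FDR threshold in percent (default 1).
#' @return filtered PSM data.frame.
#' @export
filterSignificant <- function(psms, pThreshold = 1e-15,
                              decoyPsms = NULL, fdrPercent = 1) {
  if (!nrow(psms)) return(psms)
  keep <- !is.na(psms$pValue) & psms$pValue <= pThreshold
  out <- psms[keep, , drop = FALSE]
  if (!is.null(decoyPsms) && nrow(out)) {
    cuts <- sort(unique(out$score))
    okCut <- NA_integer_
    for (s in cuts) {
      fdr <- 100 * sum(decoyPsms$score >= s) / sum(out$score >= s)
      if (fdr <= fdrPercent) { okCut <- s; break }
    }
    out <- if (is.na(okCut)) out[0, , drop = FALSE]
           else out[out$score >= okCut, , drop = FALSE]
  }
  out
}
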