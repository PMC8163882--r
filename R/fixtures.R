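#' Specification for synthetic fixtures
#'
#' Bundles the knobs of the synthetic-data generator: BGC shape (ORF count,
#' modules per ORF, substrate alphabet size per domain), spectrum degradation
#' (peak dropout fraction, uniform noise peaks, Gaussian mass jitter
#' truncated at 3 sd), peptide topology and an optional planted
#' post-assembly modification. Jitter standard deviations above half the
#' fragment tolerance make fixtures unsolvable by construction and are
#' rejected.
#'
#' @param seed integer seed controlling every random choice.
#' @param nOrfs,modulesPerOrf BGC shape (defaults 2 and 2).
#' @param alphabetSize substrate predictions per A-domain (default 3).
#' @param topology backbone topology for simulated peptides.
#' @param peakDropout fraction of theoretical peaks dropped (default 0).
#' @param noisePeaks number of uniform noise peaks added (default 0).
#' @param massJitterSd peak mass jitter sd in Da (default 0).
#' @param pamPosition,pamDelta optional planted modification.
#' @param epsilon fragment tolerance the fixture is meant to be solvable at.
#' @return a list of class \code{fixtureSpec}.
#' @export
fixtureSpec <- function(seed, nOrfs = 2L, modulesPerOrf = 2L,
                        alphabetSize = 3L, topology = "cyclic",
                        peakDropout = 0, noisePeaks = 0L, massJitterSd = 0,
                        pamPosition = NULL, pamDelta = 0, epsilon = 0.02) {
  stopifnot(peakDropout >= 0, peakDropout <= 1, noisePeaks >= 0,
            massJitterSd >= 0, nOrfs >= 1, modulesPerOrf >= 1,
            alphabetSize >= 1)
  if (massJitterSd > epsilon / 2)
    stop("massJitterSd must be at most epsilon / 2 for a solvable fixture")
  structure(list(seed = as.integer(seed), nOrfs = as.integer(nOrfs),
                 modulesPerOrf = as.integer(modulesPerOrf),
                 alphabetSize = as.integer(alphabetSize), topology = topology,
                 peakDropout = peakDropout, noisePeaks = as.integer(noisePeaks),
                 massJitterSd = massJitterSd, pamPosition = pamPosition,
                 pamDelta = pamDelta, epsilon = epsilon),
            class = "fixtureSpec")
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic BGC with a planted core NRP
#'
#' Each A-domain receives one planted substrate with perfect evidence
#' (Stachelhaus 100, single SVM prediction) and \code{alphabetSize - 1}
#' distractors with strictly weaker evidence, so the planted residue is the
#' unique per-position score maximum and the planted core attains the
#' assembly line's maximum adenylation score.
#'
#' @param spec a [fixtureSpec()].
#' @return list with elements \code{bgc} (\linkS4class{Bgc}) and \code{core}
#'   (character vector of planted residues in assembly-line order).
#' @export
makeBgc <- function(spec) {
  nPos <- spec$nOrfs * spec$modulesPerOrf
  pool <- standardResidues()
  stopifnot(nPos <= length(pool))
  withSeed(spec$seed, {
    # planted residues drawn without replacement: every position is uniquely
    # identifiable, so a planted modification position is recoverable
    core <- sample(pool, nPos)
    orfs <- list(); pos <- 0L
    for (j in seq_len(spec$nOrfs)) {
      mods <- list()
      for (m in seq_len(spec$modulesPerOrf)) {
        pos <- pos + 1L
        nd <- spec$alphabetSize - 1L
        distract <- sample(setdiff(pool, core[pos]), nd)
        mods[[m]] <- NrpsModule(
          aa = c(core[pos], distract),
          stachelhaus = c(100, if (nd) sample(55:90, nd, replace = TRUE)),
          svm_tier = c("single", if (nd) sample(c("small_cluster", "large_cluster"),
                                               nd, replace = TRUE)))
      }
      orfs[[j]] <- Orf(sprintf("orf%d", j), mods)
    }
    list(bgc = Bgc(sprintf("synthetic_bgc_seed%d", spec$seed), orfs),
         core = core)
  })
}

#' Simulate a tandem mass spectrum of a structure
#'
#' Builds the theoretical spectrum of the structure (with the planted
#' modification applied when the fixture spec carries one), protonates it,
#' then degrades it per the fixture spec: Gaussian mass jitter truncated at
#' 3 sd, peak
#' dropout, and uniform noise peaks over [50, precursor m/z]. The precursor
#' is consistent with the (modified) structure mass at charge 1.
#'
#' @param structure an \linkS4class{NrpStructure}.
#' @param spec a [fixtureSpec()].
#' @param id spectrum identifier.
#' @param seedOffset added to \code{spec$seed} so one spec can yield many
#'   distinct spectra deterministically.
#' @return a \linkS4class{Spectrum} (MGF-writable via [writeMgf()]).
#' @export
simulateSpectrum <- function(structure, spec, id = structure@id,
                             seedOffset = 0L) {
  if (!is.null(spec$pamPosition))
    structure <- variantStructure(structure, spec$pamPosition, spec$pamDelta)
  withSeed(spec$seed + seedOffset, {
    theo <- theoreticalSpectrum(structure)$mass
    mz <- sort(unique(theo)) + PROTON_MASS
    if (spec$massJitterSd > 0) {
      jit <- stats::rnorm(length(mz), 0, spec$massJitterSd)
      jit <- pmin(pmax(jit, -3 * spec$massJitterSd), 3 * spec$massJitterSd)
      mz <- mz + jit
    }
    if (spec$peakDropout > 0) {
      keep <- stats::runif(length(mz)) >= spec$peakDropout
      if (!any(keep)) keep[sample.int(length(mz), 1L)] <- TRUE
      mz <- mz[keep]
    }
    intensity <- stats::runif(length(mz), 50, 100)
    precursor <- structureMass(structure) + PROTON_MASS
    if (spec$noisePeaks > 0) {
      nmz <- stats::runif(spec$noisePeaks, 50, precursor)
      mz <- c(mz, nmz)
      intensity <- c(intensity, stats::runif(spec$noisePeaks, 1, 20))
    }
    Spectrum(id, precursor, 1L, mz, intensity)
  })
}
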