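#' Default run configuration
#'
#' All defaults follow the engine's standard operating point: precursor and
#' fragment tolerances 0.02 Da, blind-modification bound 150 Da, top-1000
#' candidate cores per assembly line under a 1e5 enumeration cap, spectra
#' with at least 20 peaks, BGCs with at least 3 A-domains, assembly lines of
#' 3-20 modules, significance p <= 1e-15, decoy FDR 1%, network cosine 0.7.
#'
#' @param ... overrides for any default field.
#' @return a named list of configuration values.
#' @export
runConfig <- function(...) {
  cfg <- list(
    mode = "orfdel",          # assembly-line generation: canonical/orfdel/orfdup/both
    searchMode = "one_vs_one",
    delta = 0.02, epsilon = 0.02, maxMod = 150,
    nCandidates = 1000L, hardCap = 100000L,
    minPeaks = 20L, minADomains = 3L,
    minModules = 3L, maxModules = 20L,
    pThreshold = 1e-15, fdrPercent = 1, cosThreshold = 0.7,
    familyPvalue = 1e-20,
    computePvalues = TRUE, nSim = 10000L, seed = 1L,
    bgcPaths = character(0), bgcFormat = "json", mgfPath = NULL,
    outDir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose top-level keys match [runConfig()] fields.
#' @return configuration list with defaults filled in.
#' @export
readConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

stageLog <- function(fmt, ...) message(sprintf(paste0("[NRPlinker] ", fmt), ...))

# Structure database for one BGC under one config: assembly lines ->
# candidate cores -> backbones -> known modifications.
bgcStructureDb <- function(bgc, cfg, massTable = residueMassTable()) {
  lines <- enumerateAssemblyLines(bgc, mode = cfg$mode,
                                  minModules = cfg$minModules,
                                  maxModules = cfg$maxModules)
  stageLog("BGC %s: %d assembly line(s)", bgc@id, length(lines))
  db <- list()
  totalBefore <- 0; totalAfter <- 0
  for (line in lines) {
    tab <- countByScore(line)
    totalBefore <- totalBefore + prod(tab@alphabetSizes)
    thr <- thresholdScore(tab, cfg$nCandidates, cfg$hardCap)
    cands <- enumerateCandidates(line, tab, thr, cfg$hardCap)
    totalAfter <- totalAfter + nrow(cands)
    lineTag <- paste(line@multiplicities, collapse = ",")
    for (r in seq_len(nrow(cands))) {
      residues <- strsplit(cands$core[r], "-", fixed = TRUE)[[1L]]
      backs <- generateBackbones(residues, hasP450 = bgc@hasP450,
                                 massTable = massTable,
                                 id = sprintf("%s|%s|%s", bgc@id, lineTag,
                                              cands$core[r]),
                                 score = cands$score[r], source = bgc@id)
      for (b in backs) db <- c(db, applyKnownModifications(b, line))
    }
  }
  stageLog("BGC %s: %s core NRP(s) before filtering, %s after, %d structure(s)",
           bgc@id, format(totalBefore, big.mark = ","),
           format(totalAfter, big.mark = ","), length(db))
  db
}

#' Run the full identification pipeline
#'
#' Executes every stage in order: BGC ingest and filtering, assembly-line
#' generation, score-based core filtering, structure generation with known
#' modifications, spectrum ingest and filtering, modification-tolerant PSM
#' search, p-value / E-value computation, significance filtering, and
#' spectral networking. Stage counts are logged throughout. When
#' \code{config$outDir} is set, the PSM table, significant PSMs and network
#' edge list are written there as TSV.
#'
#' @param config list from [runConfig()] or [readConfig()].
#' @param bgcs optional list of \linkS4class{Bgc} objects (otherwise read
#'   from \code{config$bgcPaths}).
#' @param spectra optional list of \linkS4class{Spectrum} (otherwise read
#'   from \code{config$mgfPath}).
#' @return list with elements \code{psms}, \code{significant},
#'   \code{network}, \code{counts}.
#' @export
runSearch <- function(config = runConfig(), bgcs = NULL, spectra = NULL) {
  massTable <- residueMassTable()
  if (is.null(bgcs))
    bgcs <- lapply(config$bgcPaths, readBgc, format = config$bgcFormat,
                   massTable = massTable)
  if (is.null(spectra)) {
    if (is.null(config$mgfPath)) stop("stage spectral_io: no spectra supplied")
    spectra <- readMgf(config$mgfPath)
  }
  bgcs <- Filter(Negate(is.null),
                 lapply(bgcs, filterBgc, minADomains = config$minADomains))
  stageLog("%d BGC(s) after A-domain filter", length(bgcs))
  if (!length(bgcs)) stop("stage bgc_model: no BGC passed the A-domain filter")
  spectra <- filterSpectra(spectra, config$minPeaks)
  stageLog("%d spectrum(s) after peak-count filter", length(spectra))
  if (!length(spectra)) stop("stage spectral_io: no spectrum passed the peak filter")

  dbs <- list()
  for (bgc in bgcs) {
    db <- tryCatch(bgcStructureDb(bgc, config, massTable),
                   nrplinker_unpredictable_module = function(e) {
                     warning(sprintf("skipping BGC %s: %s", bgc@id,
                                     conditionMessage(e)), call. = FALSE)
                     NULL
                   })
    if (!is.null(db)) dbs[[bgc@id]] <- db
  }
  if (!length(dbs)) stop("stage structure_gen: no structure database built")
  nStructures <- sum(lengths(dbs))

  psms <- if (config$searchMode == "one_vs_all") {
    searchDataset(spectra, dbs, mode = "one_vs_all", delta = config$delta,
                  epsilon = config$epsilon, maxMod = config$maxMod)
  } else {
    do.call(rbind, lapply(dbs, function(db)
      searchDataset(spectra, db, mode = "one_vs_one", delta = config$delta,
                    epsilon = config$epsilon, maxMod = config$maxMod)))
  }
  rownames(psms) <- NULL
  stageLog("%d PSM(s)", nrow(psms))

  if (config$computePvalues && nrow(psms)) {
    structById <- stats::setNames(unlist(dbs, recursive = FALSE),
                                  vapply(unlist(dbs, recursive = FALSE),
                                         function(s) s@id, character(1)))
    spById <- stats::setNames(spectra, vapply(spectra, function(s) s@id,
                                              character(1)))
    for (r in seq_len(nrow(psms))) {
      st <- structById[[psms$structureId[r]]]
      est <- pvalueMcmc(spById[[psms$spectrumId[r]]],
                        n = length(st@residues),
                        alphabet = standardResidues(),
                        observedScore = psms$score[r],
                        topology = st@topology, chord = st@chord,
                        nSim = config$nSim, seed = config$seed + r,
                        epsilon = config$epsilon, massTable = massTable)
      psms$pValue[r] <- est$p_value
      psms$eValue[r] <- eValue(est$p_value, length(spectra), nStructures)
    }
    psms <- psms[order(psms$spectrumId, psms$pValue), , drop = FALSE]
  }
  significant <- filterSignificant(psms, config$pThreshold)
  stageLog("%d significant PSM(s) at p <= %g", nrow(significant),
           config$pThreshold)

  network <- NULL
  sigSpectra <- spectra[vapply(spectra, function(s)
    s@id %in% significant$spectrumId, logical(1))]
  if (length(sigSpectra)) {
    clusters <- clusterSpectra(sigSpectra, config$cosThreshold,
                               epsilon = config$epsilon)
    network <- buildNetwork(sigSpectra, clusters, psms = significant,
                            cosThreshold = config$cosThreshold,
                            epsilon = config$epsilon,
                            familyPvalue = config$familyPvalue)
    stageLog("%d distinct NRP cluster(s), %d family component(s), %d reported",
             length(unique(clusters)), nrow(network@families),
             sum(network@families$reported))
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(psms, file.path(config$outDir, "psms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(significant,
                       file.path(config$outDir, "psms_significant.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(network))
      writeNetwork(network, file.path(config$outDir, "network_edges.tsv"),
                   file.path(config$outDir, "network.graphml"))
  }
  list(psms = psms, significant = significant, network = network,
       counts = list(bgcs = length(bgcs), spectra = length(spectra),
                     structures = nStructures, psms = nrow(psms),
                     significant = nrow(significant),
                     nrps = if (is.null(network)) 0L else nrow(network@nodes),
                     families = if (is.null(network)) 0L
                                else nrow(network@families)))
}
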