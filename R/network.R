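#' Modified cosine similarity of two spectra
#'
#' Cosine over a greedy one-to-one peak matching in which peak pairs may
#' align either directly or offset by the precursor mass difference, so that
#' spectra of peptides differing by a single modification still align.
#' Intensities are square-root transformed before normalization.
#'
#' @param s1,s2 \linkS4class{Spectrum} objects.
#' @param epsilon peak matching tolerance in Da (default 0.02).
#' @return similarity in [0, 1].
#' @export
modifiedCosine <- function(s1, s2, epsilon = 0.02) {
  if (!nrow(s1@peaks) || !nrow(s2@peaks)) return(0)
  w1 <- sqrt(s1@peaks[, 2L]); w1 <- w1 / sqrt(sum(w1^2))
  w2 <- sqrt(s2@peaks[, 2L]); w2 <- w2 / sqrt(sum(w2^2))
  mz1 <- s1@peaks[, 1L]; mz2 <- s2@peaks[, 1L]
  shift <- precursorNeutralMass(s1) - precursorNeutralMass(s2)
  cand <- list()
  for (off in unique(c(0, shift))) {
    d <- outer(mz1, mz2 + off, "-")
    hit <- which(abs(d) <= epsilon, arr.ind = TRUE)
    if (nrow(hit))
      cand[[length(cand) + 1L]] <-
        data.frame(i = hit[, 1L], j = hit[, 2L],
                   prod = w1[hit[, 1L]] * w2[hit[, 2L]])
  }
  if (!length(cand)) return(0)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$prod), , drop = FALSE]
  usedI <- logical(length(mz1)); usedJ <- logical(length(mz2))
  total <- 0
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (usedI[i] || usedJ[j]) next
    usedI[i] <- TRUE; usedJ[j] <- TRUE
    total <- total + cand$prod[r]
  }
  min(total, 1)
}

#' Cluster spectra into putative distinct NRPs
#'
#' Greedy single-linkage clustering: spectra whose precursors agree within
#' \code{precursorTol} and whose modified cosine reaches \code{cosThreshold}
#' fall into one cluster. The cluster count estimates the number of distinct
#' NRPs behind the identified spectra.
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param cosThreshold cosine threshold (default 0.7).
#' @param precursorTol precursor agreement tolerance in Da (default 0.02).
#' @param epsilon peak matching tolerance (Da).
#' @return integer vector of cluster labels parallel to \code{spectra}.
#' @export
clusterSpectra <- function(spectra, cosThreshold = 0.7, precursorTol = 0.02,
                           epsilon = 0.02) {
  m <- length(spectra)
  if (!m) return(integer(0))
  pm <- vapply(spectra, precursorNeutralMass, numeric(1))
  parent <- seq_len(m)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (abs(pm[i] - pm[j]) > precursorTol) next
    if (modifiedCosine(spectra[[i]], spectra[[j]], epsilon) >= cosThreshold)
      parent[find(j)] <- find(i)
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

#' Build a spectral network over spectrum clusters
#'
#' One node per cluster, represented by its highest-total-intensity member;
#' edges join representatives with modified cosine at or above the threshold
#' (any precursor shift). Connected components are putative NRP families. A
#' family is flagged \code{reported} only when it contains a PSM with
#' p-value at most \code{familyPvalue}.
#'
#' @param spectra list of \linkS4class{Spectrum}.
#' @param clusters integer cluster labels from [clusterSpectra()].
#' @param psms optional PSM data.frame (columns \code{spectrumId},
#'   \code{pValue}) used for family reporting.
#' @param cosThreshold cosine threshold for edges (default 0.7).
#' @param epsilon peak matching tolerance (Da).
#' @param familyPvalue reporting threshold (default 1e-20).
#' @return a \linkS4class{SpectralNetwork}.
#' @export
buildNetwork <- function(spectra, clusters = clusterSpectra(spectra),
                         psms = NULL, cosThreshold = 0.7, epsilon = 0.02,
                         familyPvalue = 1e-20) {
  stopifnot(length(clusters) == length(spectra))
  labels <- sort(unique(clusters))
  repIdx <- vapply(labels, function(cl) {
    members <- which(clusters == cl)
    members[which.max(vapply(members, function(i)
      sum(spectra[[i]]@peaks[, 2L]), numeric(1)))]
  }, integer(1))
  reps <- spectra[repIdx]
  nn <- length(reps)
  edges <- data.frame(from = integer(0), to = integer(0),
                      cosine = numeric(0), shift = numeric(0))
  if (nn > 1L) for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
    cs <- modifiedCosine(reps[[i]], reps[[j]], epsilon)
    if (cs >= cosThreshold)
      edges <- rbind(edges, data.frame(
        from = i, to = j, cosine = cs,
        shift = precursorNeutralMass(reps[[i]]) - precursorNeutralMass(reps[[j]])))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nn)))
  membership <- as.integer(igraph::components(g)$membership)
  bestP <- rep(NA_real_, nn)
  if (!is.null(psms) && nrow(psms)) {
    for (v in seq_len(nn)) {
      ids <- vapply(spectra[clusters == labels[v]], function(s) s@id, character(1))
      hits <- psms$pValue[psms$spectrumId %in% ids]
      if (length(hits)) bestP[v] <- min(hits, na.rm = TRUE)
    }
  }
  fam <- data.frame(family = sort(unique(membership)))
  fam$size <- vapply(fam$family, function(f) sum(membership == f), integer(1))
  fam$bestPvalue <- vapply(fam$family, function(f) {
    p <- bestP[membership == f]
    if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
  }, numeric(1))
  fam$reported <- !is.na(fam$bestPvalue) & fam$bestPvalue <= familyPvalue
  nodes <- data.frame(
    node = seq_len(nn), cluster = labels,
    representative = vapply(reps, function(s) s@id, character(1)),
    size = vapply(labels, function(cl) sum(clusters == cl), integer(1)),
    family = membership, bestPvalue = bestP, stringsAsFactors = FALSE)
  new("SpectralNetwork", nodes = nodes, edges = edges,
      membership = membership, families = fam)
}

#' Export a spectral network
#'
#' Writes the edge list as TSV and, optionally, the full network as GraphML.
#'
#' @param network a \linkS4class{SpectralNetwork}.
#' @param edgePath TSV output path for edges.
#' @param graphmlPath optional GraphML output path.
#' @return \code{edgePath}, invisibly.
#' @export
writeNetwork <- function(network, edgePath, graphmlPath = NULL) {
  utils::write.table(network@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphmlPath)) {
    g <- igraph::graph_from_data_frame(
      network@edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = network@nodes$node,
                            representative = network@nodes$representative,
                            family = network@nodes$family))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  }
  invisible(edgePath)
}
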