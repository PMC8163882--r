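# Edge list of the peptide graph: backbone path, plus the closing bond for
# cyclic topology or the side-chain chord for branch-cyclic.
peptideGraphEdges <- function(topology, n, chord = integer(0)) {
  e <- cbind(seq_len(n - 1L), 2:n)
  if (topology == "cyclic") e <- rbind(e, c(n, 1L))
  if (topology == "branch_cyclic") e <- rbind(e, chord)
  unname(e)
}

# Connected components of nodes 1..n under the edge list minus `drop`
# (indices into the edge rows). Tiny hand-rolled BFS: peptide graphs have at
# most ~20 nodes.
graphComponents <- function(edges, n, drop = integer(0)) {
  keep <- setdiff(seq_len(nrow(edges)), drop)
  adj <- vector("list", n)
  for (r in keep) {
    a <- edges[r, 1L]; b <- edges[r, 2L]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]) if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
    }
  }
  comp
}

# All fragments from bridge removals and minimal 2-edge cuts, as node sets.
# Depends only on the topology, not on residue masses, so batch scorers can
# reuse it across peptides.
fragmentNodeSets <- function(topology, n, chord = integer(0)) {
  edges <- peptideGraphEdges(topology, n, chord)
  m <- nrow(edges)
  isBridge <- vapply(seq_len(m), function(r)
    max(graphComponents(edges, n, r)) == 2L, logical(1))
  frags <- list()
  addCut <- function(drop, label) {
    comp <- graphComponents(edges, n, drop)
    if (max(comp) != 2L) return(invisible())
    for (cid in 1:2)
      frags[[length(frags) + 1L]] <<- list(nodes = which(comp == cid), cut = label)
  }
  for (r in which(isBridge))
    addCut(r, sprintf("bridge:%d-%d", edges[r, 1L], edges[r, 2L]))
  nb <- which(!isBridge)
  if (length(nb) >= 2L) {
    pairs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(pairs)))
      addCut(pairs[, p], sprintf("cut:%d-%d|%d-%d",
                                 edges[pairs[1L, p], 1L], edges[pairs[1L, p], 2L],
                                 edges[pairs[2L, p], 1L], edges[pairs[2L, p], 2L]))
  }
  frags
}

# Terminal-group offset of one fragment. The single place encoding the
# convention: only suffix fragments of a linear chain (those retaining the
# free C-terminus) carry the water of the intact termini; every other
# fragment, and every fragment of a cyclized backbone, is a bare residue sum.
# This is the unique choice under which the two fragments of any cut sum
# exactly to the structure mass for all three topologies.
fragmentWaterOffset <- function(topology, nodes, n) {
  if (topology == "linear" && n %in% nodes) WATER_MASS else 0
}

#' Theoretical spectrum of a peptide graph
#'
#' Enumerates all bridges (single-bond cuts) and minimal two-bond cuts of the
#' structure's peptide graph and records the neutral mass of every resulting
#' connected fragment. A linear n-peptide yields 2(n-1) fragments (prefixes
#' and suffixes), a head-to-tail cyclic one n(n-1) (every contiguous proper
#' substring). Masses are a multiset: deduplication happens at scoring time,
#' not here.
#'
#' @param structure an \linkS4class{NrpStructure}.
#' @return data.frame with columns \code{mass} (neutral Da), \code{cut}, and
#'   \code{fragment} (residue indices joined by \code{","}).
#' @export
theoreticalSpectrum <- function(structure) {
  n <- length(structure@residues)
  frags <- fragmentNodeSets(structure@topology, n, structure@chord)
  data.frame(
    mass = vapply(frags, function(f)
      sum(structure@masses[f$nodes]) +
        fragmentWaterOffset(structure@topology, f$nodes, n), numeric(1)),
    cut = vapply(frags, `[[`, character(1), "cut"),
    fragment = vapply(frags, function(f) paste(f$nodes, collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE)
}
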