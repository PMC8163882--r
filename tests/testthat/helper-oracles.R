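# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithmic code paths: brute-force enumeration, igraph
# connectivity, and closed-form combinatorics.

# Assembly line built directly from per-position named score vectors, e.g.
# mkLine(c(val = 100, gly = 50), c(ala = 100, leu = 100)).
mkLine <- function(..., methylation = NULL) {
  alph <- lapply(list(...), function(v)
    data.frame(aa = names(v), score = as.numeric(v), norm = as.integer(v),
               stringsAsFactors = FALSE))
  n <- length(alph)
  if (is.null(methylation)) methylation <- rep(FALSE, n)
  new("AssemblyLine", bgcId = "test", orfIds = "o1", multiplicities = 1L,
      alphabets = alph, methylation = methylation,
      epimerization = rep(FALSE, n))
}

# Brute-force core enumeration: full cartesian product with summed scores.
bruteForceCores <- function(line) {
  alph <- alphabets(line)
  grids <- expand.grid(lapply(alph, function(a) seq_len(nrow(a))),
                       KEEP.OUT.ATTRS = FALSE)
  core <- apply(grids, 1L, function(idx)
    paste(mapply(function(a, i) a$aa[i], alph, idx), collapse = "-"))
  score <- apply(grids, 1L, function(idx)
    sum(mapply(function(a, i) a$norm[i], alph, idx)))
  data.frame(core = core, score = as.integer(score), stringsAsFactors = FALSE)
}

# A random small assembly line for property tests.
randomLine <- function(n = NULL, maxAlpha = 4L) {
  if (is.null(n)) n <- sample(3:6, 1L)
  pool <- c("gly", "ala", "ser", "pro", "val", "thr", "leu", "phe")
  args <- lapply(seq_len(n), function(i) {
    k <- sample.int(maxAlpha, 1L)
    v <- sort(sample(50:100, k), decreasing = TRUE)
    v[1L] <- 100L
    stats::setNames(v, sample(pool, k))
  })
  do.call(mkLine, args)
}

# Fragment enumeration oracle via igraph: all single-edge removals that
# disconnect (bridges) and all non-bridge edge pairs whose removal
# disconnects (minimal 2-cuts), fragments as node sets.
igraphFragments <- function(topology, n, chord = integer(0)) {
  ed <- rbind(cbind(seq_len(n - 1L), 2:n),
              switch(topology, cyclic = c(n, 1L), branch_cyclic = chord, NULL))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  m <- nrow(ed)
  frags <- list()
  comps <- function(drop) igraph::components(
    igraph::delete_edges(g, drop))$membership
  isBridge <- vapply(seq_len(m), function(e) max(comps(e)) == 2L, logical(1))
  for (e in which(isBridge)) {
    cm <- comps(e)
    for (cid in 1:2) frags[[length(frags) + 1L]] <- sort(which(cm == cid))
  }
  nb <- which(!isBridge)
  if (length(nb) >= 2L) {
    prs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(prs))) {
      cm <- comps(prs[, p])
      if (max(cm) != 2L) next
      for (cid in 1:2) frags[[length(frags) + 1L]] <- sort(which(cm == cid))
    }
  }
  frags
}

# Independent variant-position maximization: rebuilds each shifted structure
# from scratch and rescans positions in reverse order.
independentVariantBest <- function(structure, spectrum, omega, epsilon = 0.02) {
  n <- length(structure@residues)
  best <- NULL
  for (i in rev(seq_len(n))) {
    if (structure@masses[i] + omega < 0) next
    st <- structure
    st@masses[i] <- st@masses[i] + omega
    sc <- spcScore(st, spectrum, epsilon)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && i < best$position))
      best <- list(position = i, score = sc)
  }
  best
}

bgcEqual <- function(a, b) {
  fa <- tempfile(fileext = ".json"); fb <- tempfile(fileext = ".json")
  on.exit(unlink(c(fa, fb)))
  writeBgc(a, fa); writeBgc(b, fb)
  identical(readLines(fa), readLines(fb))
}

# Shared residue mass table: loading it once keeps the suite fast.
MASS_TABLE <- residueMassTable()

bgcAlphabetsForTest <- function(bgc) NRPlinker:::bgcAlphabets(bgc)

# Distinct masses under the scoring resolution (1e-5 Da collapse).
distinctMassCount <- function(x) {
  x <- sort(x)
  sum(c(TRUE, diff(x) > 1e-5))
}

standardResiduesForTest <- function() {
  c("gly", "ala", "ser", "pro", "val", "thr", "cys", "leu", "ile", "asn",
    "asp", "gln", "lys", "glu", "met", "his", "phe", "arg", "tyr", "trp")
}
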