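#' Count core NRPs by adenylation score
#'
#' Bottom-up dynamic program over the assembly line's scored alphabets.
#' Cell (i, s) holds the number of length-i prefix cores with adenylation
#' score exactly s, built from the recurrence
#' \code{count(i, s) = sum_a count(i-1, s - S(i, a))} with base
#' \code{count(0, 0) = 1}. Runtime O(k n maxScore) for k the largest
#' alphabet.
#'
#' @param line an \linkS4class{AssemblyLine}.
#' @return a \linkS4class{ScoreCountTable}.
#' @export
countByScore <- function(line) {
  n <- nPositions(line)
  maxS <- 100L * n
  counts <- matrix(0, n + 1L, maxS + 1L)
  counts[1L, 1L] <- 1
  for (i in seq_len(n)) {
    prev <- counts[i, ]
    cur <- numeric(maxS + 1L)
    for (v in line@alphabets[[i]]$norm) {
      idx <- (v + 1L):(maxS + 1L)
      cur[idx] <- cur[idx] + prev[seq_len(maxS + 1L - v)]
    }
    counts[i + 1L, ] <- cur
  }
  new("ScoreCountTable", counts = counts,
      alphabetSizes = vapply(line@alphabets, nrow, integer(1)))
}

#' Adenylation score of a core NRP
#'
#' Sum of the per-position normalized specificity scores of the chosen
#' residues.
#'
#' @param line an \linkS4class{AssemblyLine}.
#' @param residues character vector of residue names, one per position.
#' @return integer score.
#' @export
adenylationScore <- function(line, residues) {
  n <- nPositions(line)
  if (length(residues) != n)
    stop(sprintf("expected %d residues, got %d", n, length(residues)))
  residues <- tolower(residues)
  total <- 0L
  for (i in seq_len(n)) {
    a <- line@alphabets[[i]]
    hit <- match(residues[i], a$aa)
    if (is.na(hit))
      lookupError("residue '%s' absent from position-%d alphabet", residues[i], i)
    total <- total + a$norm[hit]
  }
  total
}

#' Score threshold retaining the top N core NRPs
#'
#' The greatest score s' such that at least \code{nCandidates} cores have
#' adenylation score >= s'. When fewer than \code{nCandidates} cores exist in
#' total, the minimum occurring score is returned (keep everything).
#' Enumeration additionally truncates at \code{hardCap} cores in
#' descending-score order, which keeps the candidate set bounded even when
#' the score distribution has large ties.
#'
#' @param table a \linkS4class{ScoreCountTable}.
#' @param nCandidates target candidate count N (default 1000).
#' @param hardCap enumeration cap enforced by [enumerateCandidates()]
#'   (default 1e5).
#' @return integer threshold score.
#' @export
thresholdScore <- function(table, nCandidates = 1000L, hardCap = 100000L) {
  stopifnot(nCandidates >= 1L)
  n <- length(table@alphabetSizes)
  if (n == 0L) stop("empty score-count table")
  final <- table@counts[n + 1L, ]
  present <- which(final > 0) - 1L            # scores with >= 1 core
  if (!length(present)) stop("empty score-count table")
  cum <- rev(cumsum(rev(final)))              # cum[s+1] = # cores scoring >= s
  ok <- which(cum >= nCandidates) - 1L
  if (!length(ok)) return(as.integer(min(present)))
  as.integer(max(ok))
}

#' Enumerate candidate core NRPs above a score threshold
#'
#' Walks the acyclic candidate graph whose nodes are (position, score) pairs
#' with nonzero counts, emitting every source-to-sink path as a core NRP.
#' Output is in non-increasing adenylation-score order (within a score:
#' depth-first with descending per-position score, residue names breaking
#' ties lexicographically), truncated at \code{hardCap} cores. When the set
#' of cores scoring at least \code{threshold} has size <= \code{hardCap} the
#' result is exactly that set.
#'
#' @param line an \linkS4class{AssemblyLine}.
#' @param table its \linkS4class{ScoreCountTable} (recomputed when missing).
#' @param threshold minimum adenylation score.
#' @param hardCap maximum number of emitted cores (default 1e5).
#' @return data.frame with columns \code{core} (residue names joined by
#'   \code{"-"}) and \code{score}.
#' @export
enumerateCandidates <- function(line, table = countByScore(line), threshold,
                                hardCap = 100000L) {
  n <- nPositions(line)
  stopifnot(threshold <= 100L * n)
  # suffix[[i]][r + 1] = number of cores over A_i..A_n with score exactly r
  suffix <- vector("list", n + 1L)
  suffix[[n + 1L]] <- 1
  for (i in n:1) {
    span <- 100L * (n - i + 1L)
    cur <- numeric(span + 1L)
    nxt <- suffix[[i + 1L]]
    for (v in line@alphabets[[i]]$norm)
      cur[v + seq_along(nxt)] <- cur[v + seq_along(nxt)] + nxt
    suffix[[i]] <- cur
  }
  alph <- lapply(line@alphabets, function(a)
    a[order(-a$norm, a$aa), , drop = FALSE])
  cores <- character(0); scores <- integer(0)
  env <- new.env()
  env$out <- vector("list", min(hardCap, 2^16)); env$k <- 0L; env$full <- FALSE
  emit <- function(res, s) {
    env$k <- env$k + 1L
    if (env$k > length(env$out)) env$out <- c(env$out, vector("list", length(env$out)))
    env$out[[env$k]] <- list(core = paste(res, collapse = "-"), score = s)
    if (env$k >= hardCap) env$full <- TRUE
  }
  walk <- function(i, remaining, acc) {
    if (env$full) return(invisible())
    if (i > n) {
      if (remaining == 0L) emit(acc, env$target)
      return(invisible())
    }
    a <- alph[[i]]
    nxt <- suffix[[i + 1L]]
    for (r in seq_len(nrow(a))) {
      rem <- remaining - a$norm[r]
      if (rem >= 0L && rem < length(nxt) && nxt[rem + 1L] > 0) {
        walk(i + 1L, rem, c(acc, a$aa[r]))
        if (env$full) return(invisible())
      }
    }
  }
  finalRow <- table@counts[n + 1L, ]
  for (s in (100L * n):threshold) {
    if (finalRow[s + 1L] > 0) {
      env$target <- s
      walk(1L, s, character(0))
      if (env$full) break
    }
  }
  got <- env$out[seq_len(env$k)]
  data.frame(core = vapply(got, `[[`, character(1), "core"),
             score = vapply(got, function(x) as.integer(x$score), integer(1)),
             stringsAsFactors = FALSE)
}

#' Dump the final score distribution as TSV
#'
#' Writes two columns, \code{score} and \code{count}, for every score with a
#' nonzero number of cores, highest score first.
#'
#' @param table a \linkS4class{ScoreCountTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeScoreCounts <- function(table, path) {
  n <- length(table@alphabetSizes)
  final <- table@counts[n + 1L, ]
  s <- which(final > 0) - 1L
  df <- data.frame(score = rev(s), count = rev(final[s + 1L]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
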