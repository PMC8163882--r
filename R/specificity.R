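#' SVM score of a prediction tier
#'
#' Converts the hierarchical SVM prediction level of an A-domain substrate
#' into a numeric score: 100 for the single amino-acid prediction, 90 for a
#' small-cluster member, 80 for a large-cluster member, 0 when the amino acid
#' appears in none of the predicted sets.
#'
#' @param tier character vector of tiers (\code{single},
#'   \code{small_cluster}, \code{large_cluster}, \code{none}).
#' @return integer vector of scores.
#' @export
svmScore <- function(tier) {
  map <- c(single = 100L, small_cluster = 90L, large_cluster = 80L, none = 0L)
  bad <- setdiff(unique(tier), names(map))
  if (length(bad)) lookupError("unknown SVM tier(s): %s", paste(bad, collapse = ", "))
  unname(map[tier])
}

#' Specificity score of a substrate prediction
#'
#' Mean of the Stachelhaus identity and the SVM score. Predictions with
#' Stachelhaus identity not strictly above 50, or with SVM score 0, carry too
#' little evidence and are excluded (returned as \code{NA}).
#'
#' @param stachelhaus numeric vector, percent identity 0-100.
#' @param tier character vector of SVM tiers (recycled against
#'   \code{stachelhaus}).
#' @return numeric vector; \code{NA} marks excluded predictions.
#' @export
specificityScore <- function(stachelhaus, tier) {
  svm <- svmScore(tier)
  out <- (stachelhaus + svm) / 2
  out[stachelhaus <= 50 | svm == 0] <- NA_real_
  out
}

#' Normalize a scored alphabet
#'
#' Rescales the surviving specificity scores of one A-domain so that the best
#' substrate gets exactly 100: \code{norm = round(100 * score / max(score))},
#' nearest integer with halves away from zero. Normalization removes the bias
#' toward frequently observed A-domains, which attain higher absolute
#' specificity scores than rare ones.
#'
#' @param alphabet data.frame with columns \code{aa} and \code{score}
#'   (positive specificity scores; excluded predictions already dropped).
#' @return data.frame with columns \code{aa}, \code{score}, \code{norm},
#'   sorted by decreasing \code{norm} then \code{aa}.
#' @export
normalizeAlphabet <- function(alphabet) {
  if (is.null(alphabet) || nrow(alphabet) == 0L)
    stop(errorCondition("empty alphabet: module is unpredictable",
                        class = c("nrplinker_unpredictable_module", "error")))
  # duplicate residue names collapse to their best score (cartesian-product
  # semantics downstream)
  alphabet <- alphabet[order(alphabet$aa, -alphabet$score), , drop = FALSE]
  alphabet <- alphabet[!duplicated(alphabet$aa), , drop = FALSE]
  alphabet$norm <- roundHalfAway(100 * alphabet$score / max(alphabet$score))
  alphabet <- alphabet[order(-alphabet$norm, alphabet$aa), , drop = FALSE]
  rownames(alphabet) <- NULL
  alphabet[, c("aa", "score", "norm")]
}

#' Scored alphabet of one NRPS module
#'
#' Applies the Stachelhaus/SVM evidence filter, averages the surviving
#' scores, and normalizes. More than 12 surviving substrates is unusual for
#' SVM-tiered predictors and is logged but not capped.
#'
#' @param module an \linkS4class{NrpsModule}.
#' @return data.frame with columns \code{aa}, \code{score}, \code{norm}, or
#'   an error of class \code{nrplinker_unpredictable_module} when no
#'   prediction survives.
#' @export
moduleAlphabet <- function(module) {
  p <- module@predictions
  sc <- specificityScore(p$stachelhaus, p$svm_tier)
  keep <- !is.na(sc)
  if (sum(keep) > 12L)
    message(sprintf("module has %d substrates with positive SVM score (> 12)",
                    sum(keep)))
  normalizeAlphabet(data.frame(aa = p$aa[keep], score = sc[keep],
                               stringsAsFactors = FALSE))
}

# Alphabets for every module of a BGC, in ORF order. Errors with
# nrplinker_unpredictable_module if any module has an empty alphabet, which
# callers translate into skipping the whole BGC.
bgcAlphabets <- function(bgc) {
  lapply(bgc@orfs, function(o) lapply(o@modules, moduleAlphabet))
}
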