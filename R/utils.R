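# Mass-spectrometric constants shared across the package.
# Proton mass is the charge-carrier offset used for every m/z <-> neutral-mass
# conversion; water is the offset separating a free linear peptide from its
# head-to-tail cyclic form.
PROTON_MASS <- 1.00728
WATER_MASS <- 18.01056

#' Round half away from zero
#'
#' Deterministic "nearest integer" used by score normalization. \code{round()}
#' in R rounds half to even; score normalization needs a fixed, reproducible
#' tie rule, so x.5 always moves away from zero.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
roundHalfAway <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Neutral mass from precursor m/z and charge
#'
#' @param mz precursor m/z in Da.
#' @param charge positive integer charge state.
#' @return neutral monoisotopic mass in Da.
#' @export
neutralMass <- function(mz, charge) {
  stopifnot(charge >= 1)
  charge * (mz - PROTON_MASS)
}

# Internal: abort with a classed parse error carrying location info.
parseError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("nrplinker_parse_error", "error")))
}

lookupError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("nrplinker_lookup_error", "error")))
}
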