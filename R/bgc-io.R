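#' Read a BGC description
#'
#' Reads the package's documented BGC schema in either JSON or TSV form and
#' returns a \linkS4class{Bgc} with ORF and module order exactly as in the
#' file.
#'
#' JSON schema:
#' \preformatted{
#' {"id": ..., "has_p450": bool,
#'  "orfs": [{"id": ...,
#'            "modules": [{"predictions": [{"aa": ..., "stachelhaus": int,
#'                                          "svm_tier": ...}],
#'                         "methylation": bool, "epimerization": bool}]}]}
#' }
#' TSV alternative: a first comment line \code{#bgc_id=<id>  has_p450=<0|1>}
#' followed by a header and one prediction per row with columns \code{orf},
#' \code{module} (1-based index within the ORF), \code{aa},
#' \code{stachelhaus}, \code{svm_tier}, \code{methylation},
#' \code{epimerization}.
#'
#' @param path input file.
#' @param format \code{"json"} or \code{"tsv"}.
#' @param massTable residue mass table used to validate residue names.
#' @return a \linkS4class{Bgc}.
#' @export
readBgc <- function(path, format = c("json", "tsv"),
                    massTable = residueMassTable()) {
  format <- match.arg(format)
  if (!file.exists(path)) parseError("BGC file not found: %s", path)
  bgc <- if (format == "json") readBgcJson(path) else readBgcTsv(path)
  checkResidues(bgc, massTable)
  bgc
}

readBgcJson <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) parseError("malformed JSON in %s: %s",
                                                 path, conditionMessage(e)))
  for (f in c("id", "orfs")) if (is.null(doc[[f]]))
    parseError("%s: missing field '%s'", path, f)
  orfs <- lapply(doc$orfs, function(o) {
    if (is.null(o$id)) parseError("%s: ORF without id", path)
    if (length(o$modules) == 0L)
      parseError("%s: ORF '%s' has no modules", path, o$id)
    mods <- lapply(seq_along(o$modules), function(k) {
      m <- o$modules[[k]]
      if (length(m$predictions) == 0L)
        parseError("%s: ORF '%s' module %d has no predictions", path, o$id, k)
      NrpsModule(
        aa = vapply(m$predictions, function(p) as.character(p$aa), character(1)),
        stachelhaus = vapply(m$predictions, function(p) as.numeric(p$stachelhaus), numeric(1)),
        svm_tier = vapply(m$predictions, function(p) as.character(p$svm_tier), character(1)),
        methylation = isTRUE(m$methylation),
        epimerization = isTRUE(m$epimerization),
        cStarter = isTRUE(m$c_starter))
    })
    Orf(o$id, mods)
  })
  Bgc(doc$id, orfs, hasP450 = isTRUE(doc$has_p450))
}

readBgcTsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "#bgc_id="))
    parseError("%s line 1: expected '#bgc_id=<id>\\thas_p450=<0|1>'", path)
  hdr <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  kv <- strsplit(hdr, "=")
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  tab <- tryCatch(
    utils::read.delim(text = lines[-1L], stringsAsFactors = FALSE),
    error = function(e) parseError("%s: %s", path, conditionMessage(e)))
  need <- c("orf", "module", "aa", "stachelhaus", "svm_tier",
            "methylation", "epimerization")
  miss <- setdiff(need, names(tab))
  if (length(miss)) parseError("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", "))
  if (nrow(tab) == 0L) parseError("%s: no module rows", path)
  orfIds <- unique(tab$orf)
  orfs <- lapply(orfIds, function(oid) {
    sub <- tab[tab$orf == oid, , drop = FALSE]
    mods <- lapply(unique(sub$module), function(k) {
      rows <- sub[sub$module == k, , drop = FALSE]
      NrpsModule(rows$aa, rows$stachelhaus, rows$svm_tier,
                 methylation = any(as.logical(rows$methylation)),
                 epimerization = any(as.logical(rows$epimerization)))
    })
    Orf(oid, mods)
  })
  Bgc(meta[["bgc_id"]], orfs,
      hasP450 = !is.na(meta["has_p450"]) && meta[["has_p450"]] %in% c("1", "true", "TRUE"))
}

checkResidues <- function(bgc, massTable) {
  for (o in bgc@orfs) for (m in o@modules) {
    bad <- setdiff(unique(m@predictions$aa), names(massTable))
    if (length(bad))
      lookupError("BGC '%s' ORF '%s': unknown residue(s) %s",
                  bgc@id, o@id, paste(bad, collapse = ", "))
  }
  invisible(bgc)
}

#' Write a BGC description
#'
#' Inverse of [readBgc()]; writing then reading is the identity on the data
#' model.
#'
#' @param bgc a \linkS4class{Bgc}.
#' @param path output file.
#' @param format \code{"json"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeBgc <- function(bgc, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(id = bgc@id, has_p450 = bgc@hasP450,
                orfs = lapply(bgc@orfs, function(o) list(
                  id = o@id,
                  modules = lapply(o@modules, function(m) list(
                    predictions = lapply(seq_len(nrow(m@predictions)), function(i)
                      list(aa = m@predictions$aa[i],
                           stachelhaus = m@predictions$stachelhaus[i],
                           svm_tier = m@predictions$svm_tier[i])),
                    methylation = m@methylation,
                    epimerization = m@epimerization,
                    c_starter = m@cStarter)))))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    rows <- do.call(rbind, unlist(lapply(bgc@orfs, function(o)
      lapply(seq_along(o@modules), function(k) {
        m <- o@modules[[k]]
        data.frame(orf = o@id, module = k, aa = m@predictions$aa,
                   stachelhaus = m@predictions$stachelhaus,
                   svm_tier = m@predictions$svm_tier,
                   methylation = m@methylation,
                   epimerization = m@epimerization,
                   stringsAsFactors = FALSE)
      })), recursive = FALSE))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#bgc_id=%s\thas_p450=%d", bgc@id, as.integer(bgc@hasP450)), con)
    utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Parse a substrate-predictor table
#'
#' Reads NRPSpredictor2-style tabular output: tab-separated columns
#' \code{domain}, \code{aa}, \code{stachelhaus}, \code{svm_tier}, one
#' prediction per row. Duplicate (domain, aa) rows keep the higher Stachelhaus
#' value.
#'
#' @param path input TSV.
#' @return named list mapping domain id to a prediction data.frame with
#'   columns \code{aa}, \code{stachelhaus}, \code{svm_tier}.
#' @export
parsePredictorTable <- function(path) {
  tab <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) parseError("%s: %s", path, conditionMessage(e)))
  need <- c("domain", "aa", "stachelhaus", "svm_tier")
  miss <- setdiff(need, names(tab))
  if (length(miss)) parseError("%s: missing column(s) %s", path,
                               paste(miss, collapse = ", "))
  tab$aa <- tolower(tab$aa)
  out <- lapply(split(tab, tab$domain), function(sub) {
    # keep the best Stachelhaus identity per (domain, aa)
    sub <- sub[order(sub$aa, -sub$stachelhaus), , drop = FALSE]
    sub <- sub[!duplicated(sub$aa), , drop = FALSE]
    rownames(sub) <- NULL
    sub[, c("aa", "stachelhaus", "svm_tier")]
  })
  out[unique(tab$domain)]
}

#' Total A-domain count of a BGC
#' @param bgc a \linkS4class{Bgc}.
#' @return integer.
#' @export
aDomainCount <- function(bgc)
  sum(vapply(bgc@orfs, function(o) length(o@modules), integer(1)))

#' Reject BGCs with too few A-domains
#'
#' Clusters with fewer than \code{minADomains} adenylation domains carry too
#' little sequence information for confident matching and are dropped.
#'
#' @param bgc a \linkS4class{Bgc}.
#' @param minADomains minimum total A-domain count (default 3).
#' @return the input \linkS4class{Bgc}, or \code{NULL} when rejected.
#' @export
filterBgc <- function(bgc, minADomains = 3L) {
  stopifnot(minADomains >= 1L)
  if (aDomainCount(bgc) < minADomains) return(NULL)
  bgc
}
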