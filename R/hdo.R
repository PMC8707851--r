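# Hydrocarbon-degrading-organism (HDO) annotation: summing the
# proportions of genera known to contain oil-hydrocarbon degraders and
# anchoring those proportions to qPCR-derived absolute abundances.

#' Read an HDO genus database
#'
#' TSV with columns genus, domain (bacteria|archaea), evidence. The
#' bundled database covers the genera prominent in cold-seawater oil
#' degradation studies; the full literature-compiled list is pluggable
#' through `path`.
#'
#' @param path database TSV; default the bundled file.
#' @return data.frame with columns genus, domain, evidence.
#' @export
readHdoDatabase <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hdo_genera.tsv",
                        package = "taxconsensus", mustWork = TRUE)
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("genus", "domain") %in% names(db)))
    .stopf("HDO database needs columns genus, domain")
  if (nrow(db) == 0L) .stopf("HDO database is empty")
  if (anyDuplicated(db$genus))
    .stopf("duplicate genus in HDO database: %s",
           db$genus[duplicated(db$genus)][1])
  db
}

#' Summed proportion of hydrocarbon-degrader-containing genera
#'
#' @param profile a genus-level \linkS4class{TaxonomicProfile} or a named
#'   proportion vector.
#' @param db HDO database (data.frame with a genus column), default the
#'   bundled one.
#' @return list with \code{fraction} (sum of matched proportions, in
#'   [0,1]) and \code{matched} (number of matched genera).
#' @examples
#' hdoProportion(c(Pseudomonas = 0.3, Colwellia = 0.2, Unknown = 0.5))
#' @export
hdoProportion <- function(profile, db = readHdoDatabase()) {
  p <- if (is(profile, "TaxonomicProfile")) {
    if (profileLevel(profile) != "genus")
      .stopf("HDO annotation needs a genus-level profile")
    taxonProportions(profile)
  } else profile
  hit <- names(p) %in% db$genus
  list(fraction = unname(sum(p[hit])), matched = sum(hit))
}

#' Estimated absolute abundance of potential hydrocarbon degraders
#'
#' The sequencing-derived HDO fraction of the bacterial community is
#' scaled by the qPCR-measured bacterial 16S abundance (copies/mL). The
#' bacterial assay (B16S) is the anchor by default; pass the summed
#' prokaryotic abundance instead to scale against 16S_tot.
#'
#' @param hdoFraction fraction in [0, 1] from [hdoProportion()].
#' @param b16sCopiesPerMl anchoring 16S abundance, copies/mL.
#' @return estimated HDO abundance, copies/mL.
#' @examples
#' estimatedHdoAbundance(0.266, 0.845 * 1.2e6)  # ~2.7e5 copies/mL
#' @export
estimatedHdoAbundance <- function(hdoFraction, b16sCopiesPerMl) {
  if (any(hdoFraction < 0 | hdoFraction > 1))
    .stopf("hdoFraction must be in [0, 1]")
  if (any(b16sCopiesPerMl < 0)) .stopf("abundance must be >= 0")
  hdoFraction * b16sCopiesPerMl
}
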