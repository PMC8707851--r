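# Generics and accessors for the core classes.

#' @rdname TaxonomicProfile-class
#' @param object,x a TaxonomicProfile
#' @export
setGeneric("taxonProportions", function(object) standardGeneric("taxonProportions"))
#' @rdname TaxonomicProfile-class
#' @export
setMethod("taxonProportions", "TaxonomicProfile", function(object) object@proportions)

#' @rdname TaxonomicProfile-class
#' @export
setGeneric("classifiedFraction", function(object) standardGeneric("classifiedFraction"))
#' @rdname TaxonomicProfile-class
#' @export
setMethod("classifiedFraction", "TaxonomicProfile", function(object) object@classifiedFraction)

#' @rdname TaxonomicProfile-class
#' @export
setGeneric("sampleName", function(object) standardGeneric("sampleName"))
#' @rdname TaxonomicProfile-class
#' @export
setMethod("sampleName", "TaxonomicProfile", function(object) object@sample)

#' @rdname TaxonomicProfile-class
#' @export
setGeneric("methodName", function(object) standardGeneric("methodName"))
#' @rdname TaxonomicProfile-class
#' @export
setMethod("methodName", "TaxonomicProfile", function(object) object@method)

#' @rdname TaxonomicProfile-class
#' @export
setGeneric("profileLevel", function(object) standardGeneric("profileLevel"))
#' @rdname TaxonomicProfile-class
#' @export
setMethod("profileLevel", "TaxonomicProfile", function(object) object@level)

setMethod("show", "TaxonomicProfile", function(object) {
  p <- object@proportions
  cat(sprintf("TaxonomicProfile: sample %s, method %s, level %s\n",
              object@sample, object@method, object@level))
  cat(sprintf("  %d taxa; classified fraction %s\n", length(p),
              ifelse(is.na(object@classifiedFraction), "NA",
                     sprintf("%.3f", object@classifiedFraction))))
  if (length(p)) {
    top <- sort(p, decreasing = TRUE)[seq_len(min(5, length(p)))]
    cat("  top taxa:",
        paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  }
})

#' @rdname SyntheticTruth-class
#' @param object a SyntheticTruth
#' @export
setGeneric("genusAbundance", function(object) standardGeneric("genusAbundance"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("genusAbundance", "SyntheticTruth", function(object) object@abundance)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("truthDesign", function(object) standardGeneric("truthDesign"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("truthDesign", "SyntheticTruth", function(object) object@design)

#' @rdname SyntheticTruth-class
#' @export
setGeneric("genusInfo", function(object) standardGeneric("genusInfo"))
#' @rdname SyntheticTruth-class
#' @export
setMethod("genusInfo", "SyntheticTruth", function(object) object@genusInfo)

#' True per-sample relative composition of a SyntheticTruth
#'
#' @param object a \linkS4class{SyntheticTruth}.
#' @param bacterialOnly drop archaeal genera before renormalizing
#'   (classifiers in this package profile the bacterial community).
#' @return matrix genera x samples of proportions; columns sum to 1.
#' @export
setGeneric("trueProportions", function(object, bacterialOnly = TRUE)
  standardGeneric("trueProportions"))
#' @rdname trueProportions
#' @export
setMethod("trueProportions", "SyntheticTruth", function(object, bacterialOnly = TRUE) {
  ab <- object@abundance
  if (bacterialOnly) ab <- ab[!object@genusInfo$archaeal, , drop = FALSE]
  sweep(ab, 2, colSums(ab), "/")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d genera x %d samples (seed %d)\n",
              nrow(object@abundance), ncol(object@abundance), object@seed))
  cat("  treatments:",
      paste(sort(unique(object@design$treatment)), collapse = ", "),
      "; times (months):",
      paste(sort(unique(object@design$time)), collapse = ", "), "\n")
})

#' @rdname QuantResult-class
#' @param object a QuantResult
#' @export
setGeneric("quantResults", function(object) standardGeneric("quantResults"))
#' @rdname QuantResult-class
#' @export
setMethod("quantResults", "QuantResult", function(object) object@results)

#' @rdname QuantResult-class
#' @export
setGeneric("wellFits", function(object) standardGeneric("wellFits"))
#' @rdname QuantResult-class
#' @export
setMethod("wellFits", "QuantResult", function(object) object@wells)

setMethod("show", "QuantResult", function(object) {
  cat(sprintf("QuantResult: %d (sample, target) estimates from %d wells\n",
              nrow(object@results), nrow(object@wells)))
  print(utils::head(object@results, 8))
})

#' @rdname MCIAResult-class
#' @param object an MCIAResult
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname MCIAResult-class
#' @export
setMethod("eigenvalues", "MCIAResult", function(object) object@eigenvalues)

#' @rdname MCIAResult-class
#' @export
setGeneric("pseudoEigenvalues", function(object) standardGeneric("pseudoEigenvalues"))
#' @rdname MCIAResult-class
#' @export
setMethod("pseudoEigenvalues", "MCIAResult", function(object) object@pseudoEigenvalues)

#' @rdname MCIAResult-class
#' @export
setGeneric("globalScores", function(object) standardGeneric("globalScores"))
#' @rdname MCIAResult-class
#' @export
setMethod("globalScores", "MCIAResult", function(object) object@globalScores)

#' @rdname MCIAResult-class
#' @export
setGeneric("tableScores", function(object) standardGeneric("tableScores"))
#' @rdname MCIAResult-class
#' @export
setMethod("tableScores", "MCIAResult", function(object) object@tableScores)

#' @rdname MCIAResult-class
#' @export
setGeneric("varianceProportions", function(object) standardGeneric("varianceProportions"))
#' @rdname MCIAResult-class
#' @export
setMethod("varianceProportions", "MCIAResult", function(object) object@varianceProportions)

#' @rdname MCIAResult-class
#' @export
setGeneric("rvMatrix", function(object) standardGeneric("rvMatrix"))
#' @rdname MCIAResult-class
#' @export
setMethod("rvMatrix", "MCIAResult", function(object) object@rv)

setMethod("show", "MCIAResult", function(object) {
  cat(sprintf("MCIAResult: %d tables, %d axes retained\n",
              length(object@tableNames), length(object@eigenvalues)))
  cat("  eigenvalues:",
      paste(sprintf("%.4g", object@eigenvalues), collapse = ", "), "\n")
  cat("  variance proportions:",
      paste(sprintf("%.1f%%", 100 * object@varianceProportions),
            collapse = ", "), "\n")
})
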