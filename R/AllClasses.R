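#' @import methods
NULL

.checkProportions <- function(p, tol = 1e-9) {
  if (length(p) == 0L) return(TRUE)
  if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
    return("proportions must carry unique, non-empty taxon names")
  if (any(!is.finite(p)) || any(p < 0))
    return("proportions must be finite and non-negative")
  if (abs(sum(p) - 1) > tol)
    return(sprintf("proportions must sum to 1 (got %.12f)", sum(p)))
  TRUE
}

#' TaxonomicProfile: one sample profiled by one classification method
#'
#' Relative abundances of taxa among the classified bacterial (or
#' prokaryotic) reads of one sample, as reported by one taxonomic
#' classification method. Proportions are fractions over the classified,
#' non-eukaryotic taxa and sum to one; the fraction of reads the method
#' managed to classify at all is kept separately.
#'
#' @slot sample sample identifier (e.g. "SWOB4").
#' @slot method classification method name (e.g. "Kaiju", "Bracken").
#' @slot level taxonomic level: \code{"genus"} or
#'   \code{"phylum_with_proteo_classes"} (phyla with Proteobacteria split
#'   into classes).
#' @slot proportions named numeric vector, taxon -> fraction of classified
#'   reads; non-negative, sums to 1 (within 1e-9).
#' @slot classifiedFraction fraction of total reads that were classified,
#'   in [0, 1]; \code{NA} when the source format reports no unclassified
#'   count (e.g. Bracken).
#' @exportClass TaxonomicProfile
setClass("TaxonomicProfile",
  representation(
    sample = "character",
    method = "character",
    level = "character",
    proportions = "numeric",
    classifiedFraction = "numeric"
  ),
  prototype(
    level = "genus",
    proportions = numeric(0),
    classifiedFraction = NA_real_
  ),
  validity = function(object) {
    msgs <- character(0)
    chk <- .checkProportions(object@proportions)
    if (!isTRUE(chk)) msgs <- c(msgs, chk)
    cf <- object@classifiedFraction
    if (length(cf) != 1L || (!is.na(cf) && (cf < 0 || cf > 1)))
      msgs <- c(msgs, "classifiedFraction must be a single value in [0,1] or NA")
    if (!object@level %in% c("genus", "phylum_with_proteo_classes"))
      msgs <- c(msgs, "level must be 'genus' or 'phylum_with_proteo_classes'")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a TaxonomicProfile
#'
#' @param sample sample identifier.
#' @param method classification method name.
#' @param proportions named non-negative numeric vector; renormalized to
#'   sum to 1.
#' @param level taxonomic level.
#' @param classifiedFraction fraction of reads classified, or NA.
#' @return a \linkS4class{TaxonomicProfile}.
#' @export
TaxonomicProfile <- function(sample, method, proportions, level = "genus",
                             classifiedFraction = NA_real_) {
  proportions <- c(proportions)  # 1-d arrays (tapply results) -> numeric
  s <- sum(proportions)
  if (length(proportions) && s > 0) proportions <- proportions / s
  new("TaxonomicProfile", sample = sample, method = method,
      level = level, proportions = proportions,
      classifiedFraction = as.numeric(classifiedFraction))
}

#' SyntheticTruth: ground-truth community used to validate estimators
#'
#' Absolute genus abundances (16S rRNA gene copies per mL) for every
#' sample of a microcosm design (treatments SW / SWO / SWOB over time,
#' with replicates), together with the genus annotation (phylum or
#' Proteobacterial class, archaeal flag, hydrocarbon-degrader flag) and
#' the generator parameters, so downstream recovery tests need no
#' re-derivation.
#'
#' @slot design data.frame with columns \code{sample}, \code{treatment}
#'   (SW|SWO|SWOB), \code{time} (months), \code{replicate}.
#' @slot abundance numeric matrix, genera x samples, 16S copies/mL, >= 0.
#' @slot genusInfo data.frame with columns \code{genus}, \code{phylum},
#'   \code{archaeal} (logical), \code{hdo} (logical); one row per genus.
#' @slot params list of generator settings used.
#' @slot seed integer RNG seed the truth was generated from.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  representation(
    design = "data.frame",
    abundance = "matrix",
    genusInfo = "data.frame",
    params = "list",
    seed = "integer"
  ),
  validity = function(object) {
    msgs <- character(0)
    if (!all(c("sample", "treatment", "time") %in% names(object@design)))
      msgs <- c(msgs, "design needs columns sample, treatment, time")
    if (!all(object@design$treatment %in% c("SW", "SWO", "SWOB")))
      msgs <- c(msgs, "treatment labels must be SW, SWO or SWOB")
    if (any(!is.finite(object@abundance)) || any(object@abundance < 0))
      msgs <- c(msgs, "abundances must be finite and >= 0")
    if (!identical(colnames(object@abundance), object@design$sample))
      msgs <- c(msgs, "abundance columns must match design samples")
    gi <- object@genusInfo
    if (!all(c("genus", "phylum", "archaeal", "hdo") %in% names(gi)))
      msgs <- c(msgs, "genusInfo needs columns genus, phylum, archaeal, hdo")
    else {
      if (anyDuplicated(gi$genus))
        msgs <- c(msgs, "each genus must appear exactly once in genusInfo")
      if (!identical(rownames(object@abundance), gi$genus))
        msgs <- c(msgs, "abundance rows must match genusInfo genera")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' BiasModel: observation biases of one classification method
#'
#' Describes how a classification method distorts the true community when
#' it observes it: the fraction of reads it classifies at all, genera its
#' reference database lacks entirely, genus-specific multiplicative
#' over/under-sampling (reference-richness bias), the expected number of
#' spurious low-abundance false-positive genera per sample, per-genus 16S
#' copy numbers (amplicon sequencing only), and the sequencing depth.
#'
#' @slot method method name the model emulates.
#' @slot classifiedFraction fraction of reads classified, in (0, 1].
#' @slot dbMissing character vector of genera absent from the reference
#'   database (reported as zero).
#' @slot oversample named numeric vector of multiplicative biases >= 0;
#'   genera not named have factor 1.
#' @slot falsePositiveRate expected count of spurious genera per sample
#'   (Poisson mean), >= 0.
#' @slot copyNumber named numeric vector of 16S copies per genome
#'   (amplicon method only; empty otherwise).
#' @slot depth sequencing depth (reads per sample), >= 1.
#' @slot flatten PCR-competition exponent in (0, 1]: observed template
#'   shares are proportional to p^flatten before the other biases, so
#'   values below 1 compress dominant taxa (amplicon method only; 1 =
#'   no flattening).
#' @slot sampleNoiseSdlog sd (log scale) of per-sample, per-genus
#'   multiplicative observation noise — run-to-run PCR/library
#'   stochasticity beyond counting noise; 0 disables it.
#' @exportClass BiasModel
setClass("BiasModel",
  representation(
    method = "character",
    classifiedFraction = "numeric",
    dbMissing = "character",
    oversample = "numeric",
    falsePositiveRate = "numeric",
    copyNumber = "numeric",
    depth = "numeric",
    flatten = "numeric",
    sampleNoiseSdlog = "numeric"
  ),
  prototype(classifiedFraction = 1, dbMissing = character(0),
            oversample = numeric(0), falsePositiveRate = 0,
            copyNumber = numeric(0), depth = 1e5, flatten = 1,
            sampleNoiseSdlog = 0),
  validity = function(object) {
    msgs <- character(0)
    cf <- object@classifiedFraction
    if (length(cf) != 1L || is.na(cf) || cf <= 0 || cf > 1)
      msgs <- c(msgs, "classifiedFraction must be in (0, 1]")
    if (any(object@oversample < 0, na.rm = TRUE))
      msgs <- c(msgs, "oversample factors must be >= 0")
    if (object@falsePositiveRate < 0)
      msgs <- c(msgs, "falsePositiveRate must be >= 0")
    if (object@depth < 1)
      msgs <- c(msgs, "depth must be >= 1")
    if (length(object@flatten) != 1L || object@flatten <= 0 ||
        object@flatten > 1)
      msgs <- c(msgs, "flatten must be in (0, 1]")
    if (object@sampleNoiseSdlog < 0)
      msgs <- c(msgs, "sampleNoiseSdlog must be >= 0")
    if (length(object@copyNumber) && any(object@copyNumber <= 0))
      msgs <- c(msgs, "copy numbers must be > 0")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct a BiasModel
#'
#' @param method method name.
#' @param classifiedFraction fraction of reads classified, (0, 1].
#' @param dbMissing genera absent from the method's reference database.
#' @param oversample named multiplicative bias factors (>= 0).
#' @param falsePositiveRate expected spurious genera per sample.
#' @param copyNumber named 16S copies per genome (amplicon only).
#' @param depth reads per sample.
#' @param flatten PCR-competition exponent in (0, 1].
#' @param sampleNoiseSdlog per-sample multiplicative noise sd (log
#'   scale).
#' @return a \linkS4class{BiasModel}.
#' @export
biasModel <- function(method, classifiedFraction = 1,
                      dbMissing = character(0), oversample = numeric(0),
                      falsePositiveRate = 0, copyNumber = numeric(0),
                      depth = 1e5, flatten = 1, sampleNoiseSdlog = 0) {
  new("BiasModel", method = method,
      classifiedFraction = classifiedFraction, dbMissing = dbMissing,
      oversample = oversample, falsePositiveRate = falsePositiveRate,
      copyNumber = copyNumber, depth = depth, flatten = flatten,
      sampleNoiseSdlog = sampleNoiseSdlog)
}

#' CurveParams: parameters of one simulated qPCR amplification curve
#'
#' Logistic amplification with a linearly drifting baseline:
#' \deqn{F_c = base + drift \cdot c +
#'   \frac{F_{max} N_0 E^c}{F_{max} + N_0 (E^c - 1)} + \varepsilon}
#' so the pre-plateau phase is exponential with per-cycle efficiency E and
#' the curve saturates at \code{fmax}.
#'
#' @slot n0 initial template in fluorescence units (> 0 for amplifying
#'   wells; 0 for true negatives).
#' @slot efficiency per-cycle amplification efficiency E in (1, 2].
#' @slot baseline constant baseline fluorescence level.
#' @slot drift linear baseline drift per cycle.
#' @slot fmax plateau fluorescence, > baseline.
#' @slot noiseSd additive Gaussian noise sd, >= 0.
#' @slot cycles number of cycles (>= 15 recommended).
#' @exportClass CurveParams
setClass("CurveParams",
  representation(n0 = "numeric", efficiency = "numeric",
                 baseline = "numeric", drift = "numeric", fmax = "numeric",
                 noiseSd = "numeric", cycles = "integer"),
  prototype(baseline = 0.02, drift = 0, fmax = 10, noiseSd = 0,
            cycles = 40L),
  validity = function(object) {
    msgs <- character(0)
    if (object@efficiency <= 1 || object@efficiency > 2)
      msgs <- c(msgs, "efficiency must be in (1, 2]")
    if (object@fmax <= object@baseline)
      msgs <- c(msgs, "fmax must exceed baseline")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
    if (object@n0 < 0) msgs <- c(msgs, "n0 must be >= 0")
    if (length(msgs)) msgs else TRUE
  }
)

#' Construct CurveParams
#'
#' @param n0 initial template (fluorescence-equivalent units).
#' @param efficiency per-cycle efficiency E in (1, 2].
#' @param baseline constant baseline level.
#' @param drift linear baseline drift per cycle.
#' @param fmax plateau fluorescence.
#' @param noiseSd additive noise sd.
#' @param cycles number of cycles.
#' @return a \linkS4class{CurveParams}.
#' @export
curveParams <- function(n0, efficiency = 1.9, baseline = 0.02, drift = 0,
                        fmax = 10, noiseSd = 0, cycles = 40L) {
  new("CurveParams", n0 = n0, efficiency = efficiency, baseline = baseline,
      drift = drift, fmax = fmax, noiseSd = noiseSd,
      cycles = as.integer(cycles))
}

#' QuantResult: qPCR quantification of one or more (sample, target) pairs
#'
#' Gene copies per mL of water plus provenance: the assay efficiency used,
#' per-well efficiencies and N0 estimates, how many wells entered the
#' estimate, and quality flags.
#'
#' @slot results data.frame with columns \code{sample}, \code{target},
#'   \code{copies_per_reaction}, \code{copies_per_ml}, \code{efficiency},
#'   \code{wells_used}, \code{flags}.
#' @slot wells data.frame of per-well fits: \code{well}, \code{target},
#'   \code{role}, \code{sample}, \code{efficiency}, \code{n0}, \code{r2},
#'   \code{flag}.
#' @slot volumes list with \code{elution_ul}, \code{template_ul},
#'   \code{water_ml}.
#' @exportClass QuantResult
setClass("QuantResult",
  representation(results = "data.frame", wells = "data.frame",
                 volumes = "list"),
  validity = function(object) {
    msgs <- character(0)
    r <- object@results
    need <- c("sample", "target", "copies_per_reaction", "copies_per_ml",
              "efficiency", "wells_used", "flags")
    if (!all(need %in% names(r)))
      msgs <- c(msgs, paste("results needs columns:",
                            paste(need, collapse = ", ")))
    else {
      if (any(r$copies_per_ml < 0, na.rm = TRUE))
        msgs <- c(msgs, "copies_per_ml must be >= 0")
      bad <- !is.na(r$efficiency) &
        (r$efficiency <= 1 | r$efficiency > 2.2) & !nzchar(r$flags)
      if (any(bad))
        msgs <- c(msgs, "efficiency outside (1, 2.2] must be flagged")
    }
    if (length(msgs)) msgs else TRUE
  }
)

#' MCIAResult: multiple co-inertia analysis of K matched tables
#'
#' Joint ordination of K sample-matched variable tables. Per axis f the
#' analysis maximizes the sum over tables of squared covariances between a
#' table score \eqn{X_k u_k} and a common reference (global) score; the
#' maximum is the axis eigenvalue and the per-table squared covariances
#' are its pseudo-eigenvalues.
#'
#' @slot eigenvalues numeric, lambda_1 >= lambda_2 >= ... >= 0 for the
#'   retained axes.
#' @slot fullSpectrum all eigenvalues of the joint operator (for variance
#'   proportions).
#' @slot pseudoEigenvalues matrix, tables x axes; column sums equal the
#'   eigenvalues.
#' @slot varianceProportions fraction of total (full-spectrum) variance
#'   per retained axis.
#' @slot globalScores matrix, samples x axes (unit-variance reference
#'   scores scaled by sqrt(eigenvalue)).
#' @slot tableScores list of samples x axes matrices, one per table.
#' @slot loadings list of variables x axes matrices (unit-norm axes), one
#'   per table.
#' @slot rv K x K RV coefficient matrix of the preprocessed tables.
#' @slot tableNames names of the K tables.
#' @exportClass MCIAResult
setClass("MCIAResult",
  representation(eigenvalues = "numeric", fullSpectrum = "numeric",
                 pseudoEigenvalues = "matrix",
                 varianceProportions = "numeric", globalScores = "matrix",
                 tableScores = "list", loadings = "list", rv = "matrix",
                 tableNames = "character"),
  validity = function(object) {
    msgs <- character(0)
    ev <- object@eigenvalues
    if (length(ev) && (any(ev < -1e-12) || is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-10)))
      msgs <- c(msgs, "eigenvalues must be non-negative and non-increasing")
    if (length(ev) && ncol(object@pseudoEigenvalues) == length(ev)) {
      if (any(abs(colSums(object@pseudoEigenvalues) - ev) > 1e-8))
        msgs <- c(msgs, "pseudo-eigenvalues must sum to the eigenvalue per axis")
    }
    rv <- object@rv
    if (length(rv)) {
      if (max(abs(rv - t(rv))) > 1e-8 || any(abs(diag(rv) - 1) > 1e-8) ||
          any(rv < -1e-8) || any(rv > 1 + 1e-8))
        msgs <- c(msgs, "RV matrix must be symmetric with unit diagonal and entries in [0,1]")
    }
    if (length(msgs)) msgs else TRUE
  }
)
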