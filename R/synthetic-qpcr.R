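# qPCR plate simulator: logistic amplification curves with known initial
# template, per-well efficiency, baseline drift, plateau and noise, plus
# a standard dilution series per target, written in the plate CSV /
# metadata TSV layout the quantification module reads.

#' Standard dilution series
#'
#' Eight standards log-evenly spaced over the assay's dynamic range,
#' 25 to 1e8 target-gene copies per reaction.
#'
#' @param from,to range of copies per reaction.
#' @param n number of standard points.
#' @return numeric vector of copies per reaction.
#' @export
standardSeries <- function(from = 25, to = 1e8, n = 8) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Simulate one amplification curve
#'
#' \eqn{F_c = base + drift \cdot c + F_{max} N_0 E^c / (F_{max} + N_0 (E^c - 1)) + \varepsilon},
#' the logistic model whose pre-plateau phase is exactly exponential with
#' per-cycle efficiency E (the regime the window-of-linearity method
#' fits).
#'
#' @param params a \linkS4class{CurveParams}.
#' @return numeric vector of fluorescence readings, one per cycle.
#' @examples
#' f <- simulateCurve(curveParams(n0 = 1e-6, efficiency = 2, baseline = 0,
#'                                fmax = 1e6))
#' f[11] / f[10]  # doubles each cycle pre-plateau
#' @export
simulateCurve <- function(params) {
  stopifnot(is(params, "CurveParams"))
  cyc <- seq_len(params@cycles)
  amp <- if (params@n0 > 0) {
    ec <- params@efficiency^cyc
    params@fmax * params@n0 * ec / (params@fmax + params@n0 * (ec - 1))
  } else rep(0, length(cyc))
  f <- params@baseline + params@drift * cyc + amp
  if (params@noiseSd > 0)
    f <- f + stats::rnorm(length(cyc), sd = params@noiseSd)
  f
}

#' Generate a synthetic qPCR plate
#'
#' One target at a time or several: for each target a standard series
#' (default 25 to 1e8 copies), triplicate sample wells with known true
#' copies, and a no-template control. True copies are recorded in a truth
#' sidecar; curves follow [simulateCurve()] with per-well efficiency
#' jitter.
#'
#' @param sampleCopies named list: target -> named numeric vector of true
#'   copies per reaction for each sample.
#' @param standards copies per reaction of the standard series (>= 2
#'   points).
#' @param seed integer seed.
#' @param efficiency mean per-cycle efficiency in (1, 2].
#' @param efficiencySd per-well sd of the efficiency.
#' @param baseline,drift,fmax,noiseSd,cycles curve parameters (noiseSd is
#'   absolute; defaults to 1\% of fmax).
#' @param fluorPerCopy fluorescence-equivalent units per template copy.
#' @param replicates sample-well replicates (standards get one well each).
#' @param autoDilute samples above this copy number per reaction are
#'   diluted in decade steps to stay on scale (as a lab would); the
#'   dilution factor is recorded in the metadata and undone by
#'   [quantify()].
#' @return list with \code{plate} (well, target, cycle, fluorescence),
#'   \code{meta} (well, target, role, sample, known_copies,
#'   template_volume_ul) and \code{truth} (sample, target, true_copies).
#' @export
generateQpcrPlate <- function(sampleCopies, standards = standardSeries(),
                              seed = 1L, efficiency = 1.85,
                              efficiencySd = 0.01, baseline = 0.02,
                              drift = 0, fmax = 10, noiseSd = 0.01 * fmax,
                              cycles = 40L, fluorPerCopy = 1e-10,
                              replicates = 3L, autoDilute = 1e7) {
  if (length(standards) < 2) .stopf("standard series needs >= 2 points")
  if (cycles < 15) .stopf("need >= 15 cycles")
  if (!is.list(sampleCopies)) sampleCopies <- list(target = sampleCopies)

  .withOpSeed(seed, "generate_qpcr", {
    plate <- list(); meta <- list(); truth <- list(); w <- 0L
    addWell <- function(target, role, sample, copies) {
      w <<- w + 1L
      well <- sprintf("W%03d", w)
      dil <- 1
      if (role == "sample" && copies > autoDilute)
        dil <- 10^ceiling(log10(copies / autoDilute))
      e <- min(2, max(1.05, stats::rnorm(1, efficiency, efficiencySd)))
      cp <- curveParams(n0 = copies / dil * fluorPerCopy, efficiency = e,
                        baseline = baseline, drift = drift, fmax = fmax,
                        noiseSd = noiseSd, cycles = cycles)
      f <- simulateCurve(cp)
      plate[[w]] <<- data.frame(well = well, target = target,
                                cycle = seq_len(cycles), fluorescence = f)
      meta[[w]] <<- data.frame(well = well, target = target, role = role,
                               sample = sample,
                               known_copies = if (role == "standard") copies else NA_real_,
                               template_volume_ul = 1, dilution = dil)
      invisible(well)
    }
    for (target in names(sampleCopies)) {
      for (s in standards) addWell(target, "standard", NA_character_, s)
      sc <- sampleCopies[[target]]
      for (nm in names(sc)) {
        for (r in seq_len(replicates)) addWell(target, "sample", nm, sc[[nm]])
        truth[[length(truth) + 1L]] <-
          data.frame(sample = nm, target = target, true_copies = sc[[nm]])
      }
      addWell(target, "ntc", NA_character_, 0)
    }
    list(plate = do.call(rbind, plate), meta = do.call(rbind, meta),
         truth = do.call(rbind, truth))
  })
}

#' Write a plate to CSV + metadata TSV
#'
#' @param plate result of [generateQpcrPlate()].
#' @param platePath CSV path (well,target,cycle,fluorescence).
#' @param metaPath TSV path (well,target,role,sample,known_copies,
#'   template_volume_ul).
#' @return invisible paths.
#' @export
writePlate <- function(plate, platePath, metaPath) {
  utils::write.csv(plate$plate, platePath, row.names = FALSE, quote = FALSE)
  utils::write.table(plate$meta, metaPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(platePath, metaPath))
}

#' Read a plate CSV + metadata TSV
#'
#' @param platePath,metaPath paths as written by [writePlate()].
#' @return list with \code{plate} and \code{meta} data.frames.
#' @export
readPlate <- function(platePath, metaPath) {
  list(plate = utils::read.csv(platePath, stringsAsFactors = FALSE),
       meta = utils::read.delim(metaPath, stringsAsFactors = FALSE))
}
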