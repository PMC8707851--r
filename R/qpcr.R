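# Window-of-linearity qPCR analysis: per-well baseline estimation, search
# for the log-linear segment of the amplification curve, per-well
# efficiency and initial-template (N0) estimates, and multi-point
# standard-curve quantification to gene copies per mL of water.

#' Window-of-linearity configuration
#'
#' @param windowWidths candidate window widths (consecutive cycles).
#' @param r2Floor minimum R-squared of log10(F) vs cycle; wells below it
#'   are excluded from quantification.
#' @param baselineCycles early cycles used for the initial baseline.
#' @param baselineSteps number of downward baseline adjustment steps
#'   tried on each side of the initial estimate.
#' @param noAmpFactor a curve must rise this many noise-sd above the
#'   baseline to count as amplification.
#' @param plateauFraction upper cutoff: only signal below this fraction
#'   of the curve maximum enters the window search.
#' @param efficiencyOutlier wells whose efficiency deviates more than
#'   this (absolute) from the per-target median are excluded from the
#'   mean assay efficiency.
#' @return list of settings for [windowOfLinearity()] and [quantify()].
#' @export
wolConfig <- function(windowWidths = 4:6, r2Floor = 0.99,
                      baselineCycles = 3:8, baselineSteps = 10,
                      noAmpFactor = 10, plateauFraction = 0.9,
                      efficiencyOutlier = 0.05) {
  list(windowWidths = windowWidths, r2Floor = r2Floor,
       baselineCycles = baselineCycles, baselineSteps = baselineSteps,
       noAmpFactor = noAmpFactor, plateauFraction = plateauFraction,
       efficiencyOutlier = efficiencyOutlier)
}

# weighted linear fit of y on x returning slope, intercept, r2 without
# lm() overhead; weights account for noise amplification by the log and
# plateau back-transform (var(log s~) grows as 1/(s(1-s/Fhat))^2)
.linfit <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  sxx <- sum(w * (x - mx)^2); sxy <- sum(w * (x - mx) * (y - my))
  syy <- sum(w * (y - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 0 else (sxy^2 / (sxx * syy))
  c(slope = slope, intercept = my - slope * mx, r2 = r2)
}

# best log-linear window for one transformed signal with validity mask;
# windows are scored by (meets the R2 floor) x width first, then R2, so
# a wide window passing the floor beats a narrow noise-overfit one, and
# only slopes in the physically plausible efficiency band are eligible
.bestWindow <- function(s, valid, config, weights = NULL) {
  n <- length(s)
  slopeLim <- log10(c(1.05, 2.3))
  best <- NULL
  for (w in sort(config$windowWidths, decreasing = TRUE)) {
    if (w > n) next
    for (start in seq_len(n - w + 1)) {
      idx <- start:(start + w - 1)
      if (!all(valid[idx])) next
      fit <- .linfit(idx, log10(s[idx]), weights[idx])
      if (!is.finite(fit[["r2"]]) || fit[["r2"]] <= 0) next
      if (fit[["slope"]] < slopeLim[1] || fit[["slope"]] > slopeLim[2])
        next
      score <- (fit[["r2"]] >= config$r2Floor) * w + fit[["r2"]]
      if (is.null(best) || score > best$score) {
        best <- list(window = idx, slope = fit[["slope"]],
                     intercept = fit[["intercept"]], r2 = fit[["r2"]],
                     score = score)
      }
    }
  }
  best
}

#' Window-of-linearity fit of one amplification curve
#'
#' The baseline is estimated from early cycles and then iteratively
#' adjusted (including down to zero) to maximize the R-squared of the
#' log-linear window; the window is the run of 4-6 consecutive cycles in
#' the exponential phase (above the noise floor, below the plateau
#' fraction of the maximum) with the highest R-squared of log10(F)
#' against cycle. The efficiency is E = 10^slope and the per-well initial
#' template is N0 = F_q / E^Cq, which at the well's own fitted line
#' equals 10^intercept.
#'
#' @param fluor numeric vector of fluorescence by cycle.
#' @param config a [wolConfig()].
#' @return list with \code{efficiency}, \code{n0}, \code{intercept}
#'   (log10 N0), \code{window} (cycle indices), \code{r2},
#'   \code{baseline} (subtracted values), \code{noise} and \code{flag}
#'   ("" | "no-amplification" | "low-r2").
#' @examples
#' fit <- windowOfLinearity(2^(1:30))
#' fit$efficiency  # 2
#' @export
windowOfLinearity <- function(fluor, config = wolConfig()) {
  n <- length(fluor)
  if (n < 15) .stopf("need >= 15 cycles")
  if (any(!is.finite(fluor))) .stopf("fluorescence must be finite")
  cyc <- seq_len(n)
  bc <- intersect(config$baselineCycles, cyc)
  # shrink the baseline window when amplification starts early (high
  # template): cycles past the take-off would contaminate the estimate
  crude <- .linfit(2:7, fluor[2:7])
  crudeSd <- stats::sd(fluor[2:7] - (crude[["intercept"]] +
                                       crude[["slope"]] * (2:7)))
  off <- fluor - (crude[["intercept"]] + crude[["slope"]] * cyc)
  onset <- which(off > max(10 * crudeSd, 1e-9 * max(abs(fluor), 1)))
  if (length(onset) && min(onset) - 2 >= 5)
    bc <- 2:min(min(onset) - 2, max(bc))
  base0 <- .linfit(bc, fluor[bc])
  baseLine <- base0[["intercept"]] + base0[["slope"]] * cyc
  noise <- stats::sd(fluor[bc] - baseLine[bc])
  if (!is.finite(noise)) noise <- 0

  excess <- max(fluor - baseLine)
  if (excess < max(config$noAmpFactor * noise, 1e-9 * max(abs(fluor), 1),
                   .Machine$double.eps)) {
    return(list(efficiency = NA_real_, n0 = NA_real_,
                intercept = NA_real_, window = integer(0), r2 = NA_real_,
                baseline = baseLine, noise = noise,
                flag = "no-amplification"))
  }

  # candidate baselines: a constant estimated from the early cycles with
  # lowered/raised offsets, plus zero (curves recorded baseline-free).
  # The early-cycle slope is only kept when the drift is statistically
  # unambiguous: extrapolating a noise-fitted slope into the late
  # exponential phase corrupts the window far more than ignoring a
  # small true drift.
  k <- config$baselineSteps
  offsets <- noise * seq(-k, k) / 2
  slopeSe <- if (length(bc) > 2 && noise > 0)
    noise / sqrt(sum((bc - mean(bc))^2)) else Inf
  baseModel <- if (is.finite(slopeSe) &&
                   abs(base0[["slope"]]) > 4 * slopeSe)
    baseLine else rep(mean(fluor[bc]), n)
  candidates <- c(
    lapply(offsets, function(d) baseModel + d),
    list(baseLine, rep(min(fluor), n), rep(0, n)))
  # plateau compensation: the exponential template x = N0 E^c saturates
  # as s = Fmax x / (Fmax + x), so x is recovered from the signal by
  # s / (1 - s / Fhat). Fhat comes from the logistic step map
  # (1/s_{c+1} linear in 1/s_c); Fhat = Inf (no compensation) is tried
  # first and wins exact exponentials outright on R-squared
  best <- NULL
  for (b in candidates) {
    s <- fluor - b
    smax <- max(s, na.rm = TRUE)
    if (smax <= 0) next
    floorSig <- if (noise > 0) 3 * noise else 0
    pe <- .estimatePlateau(s, noise)
    fhats <- unique(c(Inf, if (is.finite(pe$fhat) && pe$fhat > smax)
      pe$fhat, smax / 0.99))
    for (fhat in fhats) {
      valid <- is.finite(s) & s > floorSig &
        s <= config$plateauFraction * min(smax, fhat)
      st <- ifelse(valid, s / pmax(1 - s / fhat, .Machine$double.eps), NA)
      ws <- ifelse(valid, (s * pmax(1 - s / fhat, 0))^2, 0)
      w <- .bestWindow(st, valid, config, weights = ws)
      if (is.null(w)) next
      if (is.null(best) || w$score > best$fit$score)
        best <- list(fit = w, baseline = b, mapE = pe$e)
    }
  }
  if (is.null(best))
    return(list(efficiency = NA_real_, n0 = NA_real_,
                intercept = NA_real_, window = integer(0), r2 = NA_real_,
                baseline = baseLine, noise = noise,
                flag = "no-amplification"))
  fit <- best$fit
  eff <- 10^fit$slope
  # the step-map slope is a nearly unbiased second estimate of the
  # per-cycle ratio; averaging it with the window slope stabilizes the
  # efficiency (on exact curves both estimates coincide)
  if (is.finite(best$mapE) && best$mapE > 1 && best$mapE <= 2.2)
    eff <- (eff + best$mapE) / 2
  # anchor N0 at the window centre so the efficiency update moves the
  # intercept consistently: N0 = F(c*) / E^c*
  cstar <- mean(fit$window)
  intercept <- fit$intercept + fit$slope * cstar - log10(eff) * cstar
  flag <- ""
  if (fit$r2 < config$r2Floor) flag <- "low-r2"
  else if (eff <= 1 || eff > 2.2) flag <- "implausible-efficiency"
  list(efficiency = eff, n0 = 10^intercept, intercept = intercept,
       window = fit$window, r2 = fit$r2, baseline = best$baseline,
       noise = noise, flag = flag)
}

# plateau estimate from the logistic step map: for s following
# baseline-free logistic amplification, 1/s_{c+1} = (1/E)(1/s_c) +
# (E-1)/(E Fmax); a weighted reciprocal fit over the high-signal cycles
# yields Fmax. Returns Inf when the curve carries no usable plateau
# information (e.g. a pure exponential).
.estimatePlateau <- function(s, noise) {
  hi <- which(s > max(10 * noise, 0.15 * max(s)))
  hi <- hi[hi < length(s)]
  hi <- hi[s[hi + 1] > 0]
  if (length(hi) < 4) return(list(fhat = Inf, e = NA_real_))
  ft <- .linfit(1 / s[hi], 1 / s[hi + 1], s[hi]^4)
  eInv <- ft[["slope"]]; b <- ft[["intercept"]]
  if (eInv <= 0 || eInv >= 1 || b <= 0)
    return(list(fhat = Inf, e = NA_real_))
  list(fhat = (1 / eInv - 1) / (b / eInv), e = 1 / eInv)
}

.geomean <- function(x) exp(mean(log(x)))

#' Quantify samples against a multi-point standard curve
#'
#' Every usable well of a target is fitted with [windowOfLinearity()];
#' wells flagged no-amplification, low R-squared, or with efficiency
#' further than the outlier cutoff from the target's median are excluded.
#' The mean assay efficiency and a common quantification threshold F_q
#' (geometric mean of the wells' window-midpoint fluorescence) give
#' comparable per-well N0 = F_q / E_mean^Cq; sample copies per reaction
#' are the mean over standard points of known copies times the N0 ratio,
#' with replicate wells averaged first. Copies per mL of analyzed water
#' follow from the volumetric chain elution / template / filtered-water.
#'
#' @param plate data.frame (well, target, cycle, fluorescence).
#' @param meta data.frame (well, target, role, sample, known_copies,
#'   template_volume_ul).
#' @param targets targets to quantify (default: all in meta).
#' @param volumes list: \code{elution_ul} (DNA elution volume),
#'   \code{template_ul} (template per reaction), \code{water_ml}
#'   (filtered water volume).
#' @param config a [wolConfig()].
#' @return a \linkS4class{QuantResult}.
#' @export
quantify <- function(plate, meta, targets = unique(meta$target),
                     volumes = list(elution_ul = 100, template_ul = 1,
                                    water_ml = 900),
                     config = wolConfig()) {
  wellRows <- list(); resRows <- list()
  for (target in targets) {
    tm <- meta[meta$target == target, , drop = FALSE]
    fits <- lapply(tm$well, function(w) {
      sub <- plate[plate$well == w & plate$target == target, , drop = FALSE]
      windowOfLinearity(sub$fluorescence[order(sub$cycle)], config)
    })
    names(fits) <- tm$well
    flags <- vapply(fits, `[[`, "", "flag")
    eff <- vapply(fits, `[[`, 0, "efficiency")
    usable <- flags == "" & tm$role %in% c("standard", "sample")
    contamination <- any(tm$role == "ntc" & flags != "no-amplification")
    wideSpread <- FALSE
    if (any(usable)) {
      medE <- stats::median(eff[usable])
      cut <- config$efficiencyOutlier
      repeat {
        keep <- usable & abs(eff - medE) <= cut
        if (sum(keep & tm$role == "standard") >= 2 || cut > 0.2) break
        cut <- cut * 2
        wideSpread <- TRUE
      }
      usable <- keep
    }
    wellRows[[target]] <- data.frame(
      well = tm$well, target = target, role = tm$role, sample = tm$sample,
      efficiency = eff, r2 = vapply(fits, `[[`, 0, "r2"),
      flag = ifelse(flags != "", flags,
                    ifelse(usable, "", "efficiency-outlier")),
      stringsAsFactors = FALSE)

    stdIdx <- which(usable & tm$role == "standard")
    if (length(stdIdx) < 2) {
      .stopf("fewer than 2 usable standard wells for target '%s'", target,
             class = "unquantifiableError")
    }
    eMean <- mean(eff[usable])
    # common threshold: geometric mean of fitted window-midpoint signal
    fq <- .geomean(vapply(which(usable), function(i) {
      fit <- fits[[i]]
      mid <- mean(fit$window)
      10^(fit$intercept + log10(fit$efficiency) * mid)
    }, 0))
    cq <- vapply(seq_along(fits), function(i) {
      fit <- fits[[i]]
      if (flags[i] != "") return(NA_real_)
      (log10(fq) - fit$intercept) / log10(fit$efficiency)
    }, 0)
    n0 <- fq / eMean^cq
    wellRows[[target]]$n0 <- n0
    # calibrate the per-cycle ratio on the dilution series itself: the
    # slope of log10(known copies) vs Cq over the standards is a far
    # more precise estimate of the assay's effective efficiency than the
    # mean per-well slope, and removes the Cq-distance coupling of
    # per-well efficiency error
    stdCopies <- tm$known_copies[stdIdx]
    calFit <- .linfit(cq[stdIdx], log10(stdCopies))
    eCal <- 10^(-calFit[["slope"]])
    if (!is.finite(eCal) || eCal <= 1 || eCal > 2.3) eCal <- eMean
    for (s in unique(stats::na.omit(tm$sample))) {
      # replicate wells that amplified cleanly are quantified even when
      # their efficiency was excluded from the assay mean
      sIdx <- which(flags == "" & tm$role == "sample" &
                      !is.na(tm$sample) & tm$sample == s)
      flag <- character(0)
      if (contamination) flag <- c(flag, "ntc-amplification")
      if (wideSpread) flag <- c(flag, "wide-efficiency-spread")
      if (!length(sIdx)) {
        resRows[[paste(s, target)]] <- data.frame(
          sample = s, target = target, copies_per_reaction = NA_real_,
          copies_per_ml = NA_real_, efficiency = eMean, wells_used = 0L,
          flags = paste(c(flag, "no-usable-wells"), collapse = ","))
        next
      }
      cqs <- mean(cq[sIdx])
      # fold difference to each standard point, combined in log domain
      dil <- if ("dilution" %in% names(tm)) tm$dilution[sIdx[1]] else 1
      copies <- dil * 10^mean(log10(stdCopies) +
                                (cq[stdIdx] - cqs) * log10(eCal))
      resRows[[paste(s, target)]] <- data.frame(
        sample = s, target = target, copies_per_reaction = copies,
        copies_per_ml = copies * (volumes$elution_ul / volumes$template_ul) /
          volumes$water_ml,
        efficiency = eMean, wells_used = length(sIdx),
        flags = paste(flag, collapse = ","))
    }
  }
  new("QuantResult", results = do.call(rbind, c(resRows,
                                                make.row.names = FALSE)),
      wells = do.call(rbind, c(wellRows, make.row.names = FALSE)),
      volumes = volumes)
}

#' Derived relative abundances from qPCR quantities
#'
#' 16S_tot = B16S + A16S; archaea\% = 100 A16S / 16S_tot; genus\% = 100
#' genus / B16S (targeted genera are normalized against the bacterial
#' community).
#'
#' @param quant a \linkS4class{QuantResult} or its results data.frame
#'   with columns sample, target, copies_per_ml.
#' @param bacterialTarget,archaealTarget target labels of the bacterial
#'   and archaeal 16S assays.
#' @return data.frame: sample, target, copies_per_ml, total_16s,
#'   archaea_pct (on archaeal rows), genus_pct (on genus-assay rows).
#' @export
relativeAbundance <- function(quant, bacterialTarget = "B16S",
                              archaealTarget = "A16S") {
  df <- if (is(quant, "QuantResult")) quantResults(quant) else quant
  out <- list()
  for (s in unique(df$sample)) {
    d <- df[df$sample == s, , drop = FALSE]
    get1 <- function(t) {
      v <- d$copies_per_ml[d$target == t]
      if (length(v)) v[1] else NA_real_
    }
    b <- get1(bacterialTarget); a <- get1(archaealTarget)
    tot <- if (!is.na(b) && !is.na(a)) b + a else NA_real_
    for (i in seq_len(nrow(d))) {
      target <- d$target[i]
      genusPct <- archaeaPct <- NA_real_
      if (target == archaealTarget && !is.na(tot))
        archaeaPct <- if (tot > 0) 100 * a / tot else NA_real_
      if (!target %in% c(bacterialTarget, archaealTarget)) {
        if (!bacterialTarget %in% d$target)
          .stopf("sample '%s': genus %% needs the %s assay", s,
                 bacterialTarget)
        genusPct <- if (is.na(b) || b <= 0) NA_real_ else
          100 * d$copies_per_ml[i] / b
      }
      out[[length(out) + 1L]] <- data.frame(
        sample = s, target = target, copies_per_ml = d$copies_per_ml[i],
        total_16s = tot, archaea_pct = archaeaPct, genus_pct = genusPct)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
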