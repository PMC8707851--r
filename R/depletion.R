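# Oil-depletion arithmetic: percent depletion against an initial
# concentration, the abiotic-corrected biodegradation contribution,
# biomarker ratios, and ring-class PAH aggregation.

#' Ring-class map for the 16 priority PAHs
#'
#' Naphthalene is the two-ring representative; acenaphthylene,
#' acenaphthene, fluorene, phenanthrene and anthracene are three-ring;
#' the remaining priority PAHs fall in the >= 4-ring class.
#'
#' @return named character vector, analyte -> "2" | "3" | ">=4".
#' @export
pahRingClasses <- function() {
  c(naphthalene = "2",
    acenaphthylene = "3", acenaphthene = "3", fluorene = "3",
    phenanthrene = "3", anthracene = "3",
    fluoranthene = ">=4", pyrene = ">=4", `benz[a]anthracene` = ">=4",
    chrysene = ">=4", `benzo[b]fluoranthene` = ">=4",
    `benzo[k]fluoranthene` = ">=4", `benzo[a]pyrene` = ">=4",
    `indeno[1,2,3-cd]pyrene` = ">=4", `dibenz[a,h]anthracene` = ">=4",
    `benzo[ghi]perylene` = ">=4")
}

#' Percent depletion of an analyte
#'
#' 100 (1 - c_t / c_0). With a grouping vector (e.g. PAH ring classes),
#' concentrations are summed within group before the ratio, which equals
#' depletion of the summed concentrations.
#'
#' @param ct concentration(s) at time t (>= 0).
#' @param c0 initial concentration(s) (> 0).
#' @param group optional grouping vector; when given, `ct` and `c0` are
#'   summed per group first.
#' @return percent depletion (<= 100), per group when grouped.
#' @examples
#' percentDepletion(59, 100)  # 41
#' @export
percentDepletion <- function(ct, c0, group = NULL) {
  if (any(ct < 0) || any(c0 < 0)) .stopf("concentrations must be >= 0")
  if (!is.null(group)) {
    ct <- tapply(ct, group, sum)
    c0 <- tapply(c0, group, sum)
  }
  if (any(c0 == 0)) .stopf("initial concentration is zero")
  100 * (1 - ct / c0)
}

#' Biodegradation contribution to depletion
#'
#' Difference between depletion in a live treatment and in the sterile
#' (abiotic) control; a non-positive difference is flagged as no
#' detectable biodegradation.
#'
#' @param depletionLive live-treatment percent depletion, in [0, 100].
#' @param depletionSterile sterile-control percent depletion, in
#'   [0, 100].
#' @return percent contribution, with attribute
#'   \code{"no_detectable_biodegradation"} set to TRUE when <= 0.
#' @examples
#' biodegradationContribution(41, 29)  # 12
#' @export
biodegradationContribution <- function(depletionLive, depletionSterile) {
  if (any(depletionLive < 0 | depletionLive > 100) ||
      any(depletionSterile < 0 | depletionSterile > 100))
    .stopf("depletion percentages must be in [0, 100]")
  d <- depletionLive - depletionSterile
  attr(d, "no_detectable_biodegradation") <- d <= 0
  d
}

#' Alkane / isoprenoid biomarker ratio
#'
#' n-alkanes biodegrade faster than the isoprenoids pristane and
#' phytane, so falling n-C17/pristane and n-C18/phytane ratios indicate
#' biodegradation.
#'
#' @param alkane n-alkane concentration(s).
#' @param isoprenoid isoprenoid concentration(s) (> 0).
#' @return the ratio(s).
#' @export
biomarkerRatio <- function(alkane, isoprenoid) {
  if (any(isoprenoid <= 0)) .stopf("isoprenoid concentration must be > 0")
  alkane / isoprenoid
}

#' Is a biomarker-ratio series strictly decreasing?
#'
#' @param series numeric time series of ratios.
#' @return TRUE when every step decreases strictly.
#' @export
isMonotoneDecreasing <- function(series) {
  length(series) < 2 || all(diff(series) < 0)
}

#' Depletion metrics from a concentration table
#'
#' For each (treatment, analyte), depletion at each time is computed
#' against the same series' t = 0 concentration; when a sterilized
#' reference treatment is present its depletion is subtracted to give
#' the biodegradation contribution of the live treatments.
#'
#' @param conc data.frame (treatment, time_months, analyte,
#'   concentration); the sterilized control is identified by
#'   `sterileTreatment`.
#' @param sterileTreatment treatment code of the abiotic control.
#' @return data.frame with columns treatment, time_months, analyte,
#'   depletion_pct, biodegradation_pct (NA where no sterile reference
#'   exists).
#' @export
depletionMetrics <- function(conc, sterileTreatment = "SWOs") {
  need <- c("treatment", "time_months", "analyte", "concentration")
  if (!all(need %in% names(conc)))
    .stopf("concentration table needs columns %s",
           paste(need, collapse = ", "))
  out <- list()
  for (an in unique(conc$analyte)) {
    d <- conc[conc$analyte == an, , drop = FALSE]
    sterile <- d[d$treatment == sterileTreatment, , drop = FALSE]
    for (tr in unique(d$treatment)) {
      dd <- d[d$treatment == tr, , drop = FALSE]
      c0 <- dd$concentration[dd$time_months == 0]
      if (!length(c0)) next
      for (tm in sort(unique(dd$time_months[dd$time_months > 0]))) {
        dep <- percentDepletion(dd$concentration[dd$time_months == tm][1],
                                c0[1])
        bio <- NA_real_
        if (tr != sterileTreatment && nrow(sterile)) {
          s0 <- sterile$concentration[sterile$time_months == 0]
          st <- sterile$concentration[sterile$time_months == tm]
          if (length(s0) && length(st)) {
            sdep <- percentDepletion(st[1], s0[1])
            bio <- as.numeric(biodegradationContribution(
              max(0, min(100, dep)), max(0, min(100, sdep))))
          }
        }
        out[[length(out) + 1L]] <- data.frame(
          treatment = tr, time_months = tm, analyte = an,
          depletion_pct = dep, biodegradation_pct = bio)
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Read a concentration table TSV
#'
#' @param path TSV with columns treatment, time_months, analyte,
#'   concentration (and optionally unit); defaults to the bundled
#'   synthetic oil-concentration table.
#' @return data.frame.
#' @export
readConcentrations <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "synthetic_concentrations.tsv",
                        package = "taxconsensus", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
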