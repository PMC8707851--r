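# Ground-truth community generator.
#
# The microcosm design mirrors an Arctic-seawater oil biodegradation
# experiment: untreated seawater (SW), oil-amended seawater (SWO) and
# oil-amended biostimulated seawater (SWOB), sampled at 0, 4 and 8 months
# in duplicate microcosms. The community baseline is log-normal over
# genera; treatments act as multiplicative, genus-specific bloom factors
# per timepoint, and total prokaryotic abundance follows configured fold
# changes exactly in expectation.

#' Default marine genus catalog
#'
#' Fifty bacterial and three archaeal genera typical of cold seawater and
#' oil-degradation studies, with phylum (Proteobacteria at class level)
#' labels, archaeal flags and hydrocarbon-degrading-organism (HDO) flags
#' taken from the bundled HDO database.
#'
#' @return data.frame with columns genus, phylum, archaeal, hdo.
#' @export
defaultGenusCatalog <- function() {
  g <- list(
    # genus, phylum/class, archaeal
    c("Pseudomonas", "Gammaproteobacteria"), c("Marinomonas", "Gammaproteobacteria"),
    c("Oleispira", "Gammaproteobacteria"), c("Cycloclasticus", "Gammaproteobacteria"),
    c("Paraperlucidibaca", "Gammaproteobacteria"), c("Colwellia", "Gammaproteobacteria"),
    c("Neptunomonas", "Gammaproteobacteria"), c("Paraglaciecola", "Gammaproteobacteria"),
    c("Glaciecola", "Gammaproteobacteria"), c("Marinobacter", "Gammaproteobacteria"),
    c("Alcanivorax", "Gammaproteobacteria"), c("Thalassolituus", "Gammaproteobacteria"),
    c("Pseudoalteromonas", "Gammaproteobacteria"), c("Shewanella", "Gammaproteobacteria"),
    c("Alteromonas", "Gammaproteobacteria"), c("Halomonas", "Gammaproteobacteria"),
    c("Idiomarina", "Gammaproteobacteria"), c("Psychrobacter", "Gammaproteobacteria"),
    c("Hyphomonas", "Alphaproteobacteria"), c("Parvibaculum", "Alphaproteobacteria"),
    c("Sulfitobacter", "Alphaproteobacteria"), c("Loktanella", "Alphaproteobacteria"),
    c("Sphingorhabdus", "Alphaproteobacteria"), c("Sneathiella", "Alphaproteobacteria"),
    c("Pacificibacter", "Alphaproteobacteria"), c("Phaeobacter", "Alphaproteobacteria"),
    c("Ruegeria", "Alphaproteobacteria"), c("Octadecabacter", "Alphaproteobacteria"),
    c("Planktomarina", "Alphaproteobacteria"), c("Pelagibacter", "Alphaproteobacteria"),
    c("Sulfurimonas", "Epsilonproteobacteria"), c("Arcobacter", "Epsilonproteobacteria"),
    c("Methylophilus", "Betaproteobacteria"), c("Limnobacter", "Betaproteobacteria"),
    c("Ulvibacter", "Bacteroidetes"), c("Aequorivita", "Bacteroidetes"),
    c("Lacinutrix", "Bacteroidetes"), c("Polaribacter", "Bacteroidetes"),
    c("Flavobacterium", "Bacteroidetes"), c("Maribacter", "Bacteroidetes"),
    c("Jejudonia", "Bacteroidetes"), c("Cellulophaga", "Bacteroidetes"),
    c("Winogradskyella", "Bacteroidetes"),
    c("Dietzia", "Actinobacteria"), c("Ilumatobacter", "Actinobacteria"),
    c("Bacillus", "Firmicutes"), c("Clostridium", "Firmicutes"),
    c("Synechococcus", "Cyanobacteria"), c("Opitutus", "Verrucomicrobia"),
    c("Nitrospina", "Nitrospinae"),
    c("Methanosarcina", "Euryarchaeota", "A"),
    c("Methanococcoides", "Euryarchaeota", "A"),
    c("Nitrosopumilus", "Thaumarchaeota", "A")
  )
  df <- data.frame(
    genus = vapply(g, `[`, "", 1L),
    phylum = vapply(g, `[`, "", 2L),
    archaeal = vapply(g, function(x) length(x) == 3L, TRUE),
    stringsAsFactors = FALSE
  )
  db <- readHdoDatabase()
  df$hdo <- df$genus %in% db$genus
  df
}

#' Default microcosm design
#'
#' SW at months 0, 4, 8 and SWO/SWOB at months 4, 8, in duplicate
#' microcosms (the initial seawater SW0 is one pooled sample).
#'
#' @return data.frame with columns sample, treatment, time, replicate.
#' @export
defaultDesign <- function() {
  rows <- list(c("SW", 0, 1))
  for (tr in c("SW", "SWO", "SWOB"))
    for (tm in c(4, 8))
      for (rp in 1:2) rows <- c(rows, list(c(tr, tm, rp)))
  d <- data.frame(
    treatment = vapply(rows, `[`, "", 1L),
    time = as.numeric(vapply(rows, `[`, "", 2L)),
    replicate = as.integer(vapply(rows, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
  d$sample <- ifelse(d$time == 0, "SW0",
                     sprintf("%s%d.%d", d$treatment, d$time, d$replicate))
  d[, c("sample", "treatment", "time", "replicate")]
}

#' Default community-dynamics parameters
#'
#' Total prokaryotic abundance starts at 1.2e6 16S copies/mL (archaea
#' 15.5\% of it) and changes by treatment/time fold factors (SWOB 69- and
#' 103-fold at 4 and 8 months; SW/SWO a few-fold). Genus blooms encode the
#' observed succession: Pseudomonas/Oleispira/Marinomonas bloom in SWOB at
#' 4 months and are succeeded by Cycloclasticus/Paraperlucidibaca at 8
#' months; Hyphomonas blooms in SWO at 4 months, succeeded by
#' Colwellia/Marinomonas.
#'
#' @return list of dynamics settings accepted by [generateTruth()].
#' @export
defaultTruthParams <- function() {
  list(
    total0 = 1.2e6,             # 16S_tot copies/mL at month 0
    archaealFraction0 = 0.155,  # archaeal share of the initial community
    baselineSdlog = 1,          # log-normal baseline spread over genera
    noiseSdlog = 0.15,          # per-sample multiplicative replicate noise
    foldChange = list(
      SW = c(`0` = 1, `4` = 2.5, `8` = 3.5),
      SWO = c(`0` = 1, `4` = 3.0, `8` = 4.4),
      SWOB = c(`0` = 1, `4` = 69, `8` = 103)
    ),
    archaealFold = list(        # archaeal share multiplier vs month 0
      SW = c(`0` = 1, `4` = 0.032, `8` = 0.032),
      SWO = c(`0` = 1, `4` = 0.14, `8` = 0.14),
      SWOB = c(`0` = 1, `4` = 0.002, `8` = 0.002)
    ),
    blooms = list(
      SWO = list(`4` = c(Hyphomonas = 12, Parvibaculum = 6),
                 `8` = c(Colwellia = 8, Marinomonas = 6, Hyphomonas = 3)),
      # SWOB shares a persistently elevated degrader guild (Pseudomonas,
      # Sphingorhabdus, Dietzia, Aequorivita) across both timepoints, on
      # top of the Oleispira -> Cycloclasticus/Paraperlucidibaca
      # succession
      SWOB = list(`4` = c(Pseudomonas = 40, Oleispira = 20, Marinomonas = 12,
                          Sphingorhabdus = 10, Dietzia = 8, Aequorivita = 5),
                  `8` = c(Pseudomonas = 20, Cycloclasticus = 15,
                          Paraperlucidibaca = 12, Sphingorhabdus = 12,
                          Dietzia = 8, Aequorivita = 6, Ulvibacter = 4))
    )
  )
}

.lognormBaseline <- function(n, sdlog) {
  stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
}

#' Generate a ground-truth community
#'
#' Draws a log-normal baseline composition over the genus catalog, applies
#' treatment- and time-specific bloom multipliers, rescales every sample
#' so the configured total-abundance fold changes hold exactly in
#' expectation, and (optionally) adds multiplicative log-normal replicate
#' noise with mean one.
#'
#' @param design data.frame as from [defaultDesign()].
#' @param params dynamics settings as from [defaultTruthParams()].
#' @param seed integer seed; the same seed reproduces the truth exactly.
#' @param genusCatalog data.frame as from [defaultGenusCatalog()].
#' @param noise logical; disable to make fold changes exact.
#' @return a \linkS4class{SyntheticTruth}.
#' @examples
#' tr <- generateTruth(seed = 1, noise = FALSE)
#' colSums(genusAbundance(tr))[["SWOB8.1"]] / sum(genusAbundance(tr)[, "SW0"])
#' @export
generateTruth <- function(design = defaultDesign(),
                          params = defaultTruthParams(), seed = 1L,
                          genusCatalog = defaultGenusCatalog(),
                          noise = TRUE) {
  if (nrow(design) == 0L) .stopf("design grid must be non-empty")
  bad <- setdiff(design$treatment, c("SW", "SWO", "SWOB"))
  if (length(bad)) .stopf("invalid treatment label: %s", bad[1])
  fc <- unlist(params$foldChange)
  if (any(!is.finite(fc))) .stopf("fold-change parameters must be finite")
  if (any(fc < 0)) .stopf("negative fold change")

  .withOpSeed(seed, "generate_truth", {
    genera <- genusCatalog$genus
    arch <- genusCatalog$archaeal
    base <- .lognormBaseline(length(genera), params$baselineSdlog)
    names(base) <- genera

    ab <- matrix(0, nrow = length(genera), ncol = nrow(design),
                 dimnames = list(genera, design$sample))
    for (i in seq_len(nrow(design))) {
      tr <- design$treatment[i]; tm <- as.character(design$time[i])
      comp <- base
      bl <- params$blooms[[tr]][[tm]]
      if (length(bl)) {
        known <- intersect(names(bl), genera)
        # bloom factors scale the mean baseline, so a bloom of x means
        # "x-fold the typical genus share" irrespective of the genus's
        # own baseline draw
        comp[known] <- mean(base) * bl[known]
      }
      # split into bacterial / archaeal shares
      aShare0 <- params$archaealFraction0
      aMul <- params$archaealFold[[tr]][[tm]]
      if (is.null(aMul)) aMul <- 1
      aShare <- min(0.95, aShare0 * aMul)
      compB <- comp; compB[arch] <- 0
      compA <- comp; compA[!arch] <- 0
      if (!any(arch)) aShare <- 0
      comp <- compB / sum(compB) * (1 - aShare) +
        (if (aShare > 0) compA / sum(compA) * aShare else 0)
      fold <- params$foldChange[[tr]][[tm]]
      if (is.null(fold)) fold <- 1
      total <- params$total0 * fold
      x <- comp * total
      if (noise && params$noiseSdlog > 0) {
        s <- params$noiseSdlog
        # mean-one multiplicative noise keeps fold changes exact in expectation
        x <- x * stats::rlnorm(length(x), meanlog = -s^2 / 2, sdlog = s)
      }
      ab[, i] <- x
    }
    new("SyntheticTruth", design = design, abundance = ab,
        genusInfo = genusCatalog, params = params, seed = as.integer(seed))
  })
}

#' Write / read a ground-truth sidecar TSV
#'
#' Long-form machine-readable truth (sample, genus, abundance_copies_per_ml,
#' phylum, archaeal, hdo) so recovery tests need no re-derivation.
#'
#' @param truth a \linkS4class{SyntheticTruth}.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTruthSidecar <- function(truth, path) {
  gi <- genusInfo(truth)
  ab <- genusAbundance(truth)
  long <- do.call(rbind, lapply(colnames(ab), function(s) {
    data.frame(sample = s, genus = rownames(ab),
               abundance_copies_per_ml = ab[, s],
               phylum = gi$phylum, archaeal = gi$archaeal, hdo = gi$hdo,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
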