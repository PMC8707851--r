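# Generators for hydrocarbon-degradation-gene (HDG) read-count tables and
# MAG quality / pairwise-ANI tables with planted ground truth.

#' Default per-sample HDG abundance truth
#'
#' Total community HDG abundance (summed RPKG) per sample, distributed
#' over the bundled gene set by fixed log-normal weights. Defaults put the
#' initial seawater at a summed RPKG of 277 and let biostimulation raise
#' it 1.3-fold, the scale of change seen in nutrient-amended oiled
#' seawater.
#'
#' @param geneDefs gene definitions, see [readGeneDefs()].
#' @param samples sample IDs.
#' @param totals named summed-RPKG per sample; defaults by treatment code
#'   embedded in the sample name.
#' @return matrix gene x sample of true RPKG values.
#' @export
defaultRpkgTruth <- function(geneDefs = readGeneDefs(),
                             samples = defaultDesign()$sample,
                             totals = NULL) {
  if (is.null(totals)) {
    mult <- function(s) {
      if (grepl("^SWOB", s)) 1.3
      else if (grepl("^SWO", s)) 1.1
      else if (s == "SW0") 1.0
      else 0.95
    }
    totals <- stats::setNames(277 * vapply(samples, mult, 0), samples)
  }
  w <- .withOpSeed(99L, "rpkg_weights", {
    x <- stats::rlnorm(nrow(geneDefs), 0, 1)
    x / sum(x)
  })
  out <- outer(w, totals[samples])
  dimnames(out) <- list(geneDefs$gene, samples)
  out
}

#' Generate an HDG read-count table with known RPKG truth
#'
#' Reads are Poisson draws with mean RPKG x gene length (kb) x genome
#' equivalents, the inversion of the RPKG normalization, so the
#' community profiler can be validated against the planted values.
#'
#' @param rpkgTruth gene x sample matrix of true RPKG values.
#' @param geneDefs gene definitions with \code{gene} and \code{length_bp}.
#' @param genomeEquivalents named numeric, genome equivalents per sample.
#' @param seed integer seed.
#' @return list with \code{counts} (sample, gene, reads, gene_length_bp,
#'   genome_equivalents) and \code{truth} (the RPKG matrix).
#' @export
generateHdgCounts <- function(rpkgTruth = defaultRpkgTruth(),
                              geneDefs = readGeneDefs(),
                              genomeEquivalents = NULL, seed = 1L) {
  if (nrow(geneDefs) == 0L) .stopf("gene definitions must be non-empty")
  if (any(geneDefs$length_bp <= 0)) .stopf("nonpositive gene length")
  samples <- colnames(rpkgTruth)
  if (is.null(genomeEquivalents))
    genomeEquivalents <- stats::setNames(rep(100, length(samples)), samples)
  if (any(genomeEquivalents <= 0)) .stopf("nonpositive genome equivalents")
  len <- stats::setNames(geneDefs$length_bp, geneDefs$gene)[rownames(rpkgTruth)]
  .withOpSeed(seed, "generate_hdg", {
    rows <- lapply(samples, function(s) {
      mu <- rpkgTruth[, s] * (len / 1000) * genomeEquivalents[[s]]
      data.frame(sample = s, gene = rownames(rpkgTruth),
                 reads = stats::rpois(length(mu), mu),
                 gene_length_bp = as.numeric(len),
                 genome_equivalents = genomeEquivalents[[s]])
    })
    list(counts = do.call(rbind, rows), truth = rpkgTruth)
  })
}

#' Generate MAG quality, ANI and gene-hit tables with planted organisms
#'
#' Organisms are planted as clusters of MAGs whose pairwise ANI is drawn
#' above the dereplication threshold, while between-organism ANI stays
#' below it; each organism carries a characteristic HDG set that member
#' MAGs inherit with a per-MAG retention probability (producing the
#' partial-presence pattern of real MAG panels). A configurable fraction
#' of additional low-quality MAGs (completeness <= 50 or contamination
#' >= 10) is appended to exercise quality filtering.
#'
#' @param nOrganisms number of planted organisms (>= 1).
#' @param magsPerOrganism MAGs per organism (scalar or vector).
#' @param nLowQuality extra low-quality MAGs.
#' @param aniThreshold same-organism ANI threshold in (0, 100].
#' @param geneDefs gene definitions used for gene hits.
#' @param retention probability a member MAG keeps an organism gene.
#' @param seed integer seed.
#' @return list with \code{quality} (mag, completeness, contamination,
#'   taxonomy), \code{ani} (mag_a, mag_b, ani), \code{hits} (mag, gene)
#'   and \code{truth} (mag, organism).
#' @export
generateMags <- function(nOrganisms = 5, magsPerOrganism = 3,
                         nLowQuality = 4, aniThreshold = 95,
                         geneDefs = readGeneDefs(), retention = 0.9,
                         seed = 1L) {
  if (nOrganisms < 1) .stopf("need at least one organism")
  if (aniThreshold <= 0 || aniThreshold > 100)
    .stopf("ANI threshold outside (0, 100]")
  sizes <- rep_len(magsPerOrganism, nOrganisms)
  .withOpSeed(seed, "generate_mags", {
    mags <- character(0); org <- integer(0)
    for (o in seq_len(nOrganisms)) {
      ids <- sprintf("N%d_%d", o, seq_len(sizes[o]))
      mags <- c(mags, ids); org <- c(org, rep(o, sizes[o]))
    }
    quality <- data.frame(
      mag = mags,
      completeness = stats::runif(length(mags), 55, 99),
      contamination = stats::runif(length(mags), 0, 9),
      taxonomy = sprintf("Organism_%d", org))
    if (nLowQuality > 0) {
      lq <- data.frame(
        mag = sprintf("LQ_%d", seq_len(nLowQuality)),
        completeness = stats::runif(nLowQuality, 10, 50),
        contamination = stats::runif(nLowQuality, 10, 30),
        taxonomy = "unclassified")
      quality <- rbind(quality, lq)
    }
    ani <- if (length(mags) >= 2) {
      pairs <- utils::combn(seq_along(mags), 2)
      data.frame(
        mag_a = mags[pairs[1, ]], mag_b = mags[pairs[2, ]],
        ani = ifelse(org[pairs[1, ]] == org[pairs[2, ]],
                     stats::runif(ncol(pairs), aniThreshold, 99.9),
                     stats::runif(ncol(pairs), 70, aniThreshold - 5)))
    } else {
      data.frame(mag_a = character(0), mag_b = character(0),
                 ani = numeric(0))
    }
    clusters <- unique(geneDefs$cluster)
    hits <- do.call(rbind, lapply(seq_len(nOrganisms), function(o) {
      own <- clusters[stats::runif(length(clusters)) < 0.5]
      genes <- geneDefs$gene[geneDefs$cluster %in% own]
      do.call(rbind, lapply(mags[org == o], function(m) {
        kept <- genes[stats::runif(length(genes)) < retention]
        if (!length(kept)) return(NULL)
        data.frame(mag = m, gene = kept)
      }))
    }))
    list(quality = quality, ani = ani, hits = hits,
         truth = data.frame(mag = mags, organism = org))
  })
}
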