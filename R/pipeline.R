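# End-to-end orchestration: synthetic data -> native classifier reports
# -> harmonized profiles -> rank consensus, overlap, clr/Ward, MCIA ->
# qPCR anchoring -> HDO / HDG / MAG / depletion artifacts, with a
# deterministic manifest.

#' Default pipeline configuration
#'
#' @param seed integer seed driving every generator.
#' @param depth sequencing depth per sample for the synthetic
#'   classifiers.
#' @param topNPhyla top-list size for phylum ranks.
#' @param topNGenera pooled top-list size for genus overlap/MCIA.
#' @param mciaAxes retained MCIA axes.
#' @param aniThreshold same-organism ANI threshold.
#' @param preprocess MCIA preprocessing ("nsc" or "centerScale").
#' @return config list for [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1L, depth = 1e5, topNPhyla = 20,
                             topNGenera = 50, mciaAxes = 2,
                             aniThreshold = 95, preprocess = "nsc") {
  list(seed = as.integer(seed),
       synthetic = list(depth = depth),
       topNPhyla = topNPhyla, topNGenera = topNGenera,
       mciaAxes = mciaAxes, aniThreshold = aniThreshold,
       preprocess = preprocess)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the integrated analysis pipeline on synthetic data
#'
#' Generates a ground-truth community, observes it through the five
#' default classifier bias models (writing and re-reading each method's
#' native report format), and produces the full artifact bundle:
#' harmonized profiles, phylum rank consensus, top-genus overlap
#' regions, clr/Ward dendrograms, MCIA scores and RV matrix, qPCR
#' quantities with a sequencing-vs-quantification comparison table, HDO
#' fractions and estimated absolute abundances, RPKG tables, the MAG
#' organism x cluster presence matrix, and depletion metrics. A manifest
#' records the config hash, seed and a hash of every artifact.
#'
#' @param config list from [defaultRunConfig()] or a YAML file path with
#'   the same fields.
#' @param outDir output directory.
#' @return list with \code{artifacts} (named file paths),
#'   \code{manifest} (parsed manifest) and in-memory results
#'   (\code{truth}, \code{mcia}, \code{quant}, ...).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  seed <- config$seed

  # (1) truth
  truth <- stage("truth", generateTruth(seed = seed))
  art$truth <- writeTruthSidecar(truth, file.path(outDir, "truth.tsv"))
  catalog <- genusInfo(truth)
  phylumMap <- stats::setNames(catalog$phylum, catalog$genus)
  message(sprintf("stage truth: %d genera x %d samples", nrow(catalog),
                  nrow(truthDesign(truth))))

  # (2) observe through the five methods and round-trip native formats
  biases <- defaultBiasModels(catalog, depth = config$synthetic$depth)
  profilesByMethod <- list()
  for (m in names(biases)) {
    obs <- observeWithClassifier(truth, biases[[m]], seed = seed)
    dir <- file.path(outDir, "reports", m)
    paths <- writeClassifierReports(obs, dir, phylumMap = phylumMap)
    fmt <- switch(m, Kraken2 = "kraken2", Bracken = "bracken",
                  Kaiju = "kaiju", KaijuMAR = "kaiju", "amplicon")
    prof <- if (fmt == "amplicon") {
      readReport(paths[1], format = "amplicon", taxonomyPath = paths[2],
                 method = m)
    } else {
      setNames(lapply(seq_along(paths), function(i)
        readReport(paths[i], format = fmt, method = m,
                   sample = names(obs$samples)[i])),
        names(obs$samples))
    }
    profilesByMethod[[m]] <- prof[truthDesign(truth)$sample]
  }
  message(sprintf("stage observe: %d methods x %d samples",
                  length(profilesByMethod),
                  length(profilesByMethod[[1]])))

  # (3) harmonized genus profiles
  allProfiles <- unlist(profilesByMethod, use.names = FALSE)
  harm <- stage("harmonize", harmonizeProfiles(allProfiles))
  art$profiles <- writeHarmonizedProfiles(harm,
                                          file.path(outDir, "profiles.tsv"))

  # (4) phylum rank consensus
  rankRows <- list()
  for (s in truthDesign(truth)$sample) {
    ranksPerMethod <- lapply(names(profilesByMethod), function(m)
      rankTaxa(aggregateToPhylum(profilesByMethod[[m]][[s]], phylumMap),
               n = config$topNPhyla))
    names(ranksPerMethod) <- names(profilesByMethod)
    avg <- averageRanks(ranksPerMethod)
    for (m in names(ranksPerMethod)) {
      r <- ranksPerMethod[[m]]
      rankRows[[paste(s, m)]] <- data.frame(
        sample = s, method = m, taxon = names(r), rank = as.integer(r),
        average_rank = unname(avg[names(r)]))
    }
  }
  art$ranks <- .writeTsv(do.call(rbind, c(rankRows, make.row.names = FALSE)),
                         file.path(outDir, "rank_consensus.tsv"))

  # (5) top-genus overlap regions
  topSets <- lapply(profilesByMethod, topGenera, n = config$topNGenera)
  overlap <- topSetOverlap(topSets)
  art$overlap <- .writeTsv(
    data.frame(region = names(overlap), size = as.integer(overlap)),
    file.path(outDir, "top_genus_overlap.tsv"))

  # (6) clr + Ward dendrogram per method
  wardRows <- list()
  for (m in names(profilesByMethod)) {
    keep <- intersect(colnames(harm$matrix), topSets[[m]])
    sub <- harm$matrix[harm$info$method == m, keep, drop = FALSE]
    rownames(sub) <- harm$info$sample[harm$info$method == m]
    hc <- wardCluster(clrTransform(sub))
    wardRows[[m]] <- data.frame(method = m,
                                merge_a = hc$merge[, 1],
                                merge_b = hc$merge[, 2],
                                height = hc$height)
  }
  art$dendrograms <- .writeTsv(
    do.call(rbind, c(wardRows, make.row.names = FALSE)),
    file.path(outDir, "ward_dendrograms.tsv"))

  # (7) MCIA of per-method top-genus tables
  unionTop <- sort(unique(unlist(topSets)))
  tables <- lapply(names(profilesByMethod), function(m) {
    sub <- harm$matrix[harm$info$method == m,
                       intersect(colnames(harm$matrix), unionTop),
                       drop = FALSE]
    rownames(sub) <- harm$info$sample[harm$info$method == m]
    sub[truthDesign(truth)$sample, , drop = FALSE]
  })
  names(tables) <- names(profilesByMethod)
  mc <- stage("mcia", mciaFit(tables, nAxes = config$mciaAxes,
                              preprocess = config$preprocess))
  art$mcia_scores <- .writeTsv(
    data.frame(sample = rownames(globalScores(mc)), globalScores(mc)),
    file.path(outDir, "mcia_global_scores.tsv"))
  art$mcia_eigen <- .writeTsv(
    data.frame(axis = seq_along(eigenvalues(mc)),
               eigenvalue = eigenvalues(mc),
               variance_proportion = varianceProportions(mc)),
    file.path(outDir, "mcia_eigenvalues.tsv"))
  art$mcia_rv <- .writeTsv(
    data.frame(method = rownames(rvMatrix(mc)), rvMatrix(mc)),
    file.path(outDir, "mcia_rv.tsv"))

  # (8) qPCR quantification and sequencing-vs-quantification comparison
  ab <- genusAbundance(truth)
  arch <- catalog$archaeal
  perMlToReaction <- 900 / 100  # 900 mL filtered, 100 uL elution, 1 uL used
  samples <- truthDesign(truth)$sample
  sampleCopies <- list(
    B16S = stats::setNames(colSums(ab[!arch, ]) * perMlToReaction, samples),
    A16S = stats::setNames(colSums(ab[arch, ]) * perMlToReaction, samples))
  for (g in c("Pseudomonas", "Cycloclasticus", "Colwellia"))
    sampleCopies[[g]] <- stats::setNames(ab[g, ] * perMlToReaction, samples)
  plate <- stage("qpcr", generateQpcrPlate(sampleCopies, seed = seed))
  writePlate(plate, file.path(outDir, "plate.csv"),
             file.path(outDir, "plate_meta.tsv"))
  quant <- stage("qpcr", quantify(plate$plate, plate$meta))
  rel <- relativeAbundance(quant)
  art$qpcr <- .writeTsv(merge(quantResults(quant), rel,
                              by = c("sample", "target"), sort = TRUE),
                        file.path(outDir, "qpcr_results.tsv"))

  # comparison in the printed multi-method layout: per genus, method
  # rows (sequencing %)
  # plus a quantification row, then over/under-estimation factors
  cmpRows <- list()
  for (g in c("Pseudomonas", "Cycloclasticus", "Colwellia")) {
    for (m in names(profilesByMethod)) {
      pct <- vapply(samples, function(s) {
        p <- taxonProportions(profilesByMethod[[m]][[s]])
        100 * (if (g %in% names(p)) p[[g]] else 0)
      }, 0)
      cmpRows[[paste(g, m)]] <- data.frame(genus = g, method = m,
                                           sample = samples,
                                           proportion_pct = pct)
    }
    qp <- rel[rel$target == g, c("sample", "genus_pct")]
    cmpRows[[paste(g, "Quantification")]] <- data.frame(
      genus = g, method = "Quantification", sample = qp$sample,
      proportion_pct = qp$genus_pct)
  }
  cmp <- do.call(rbind, c(cmpRows, make.row.names = FALSE))
  quantRows <- cmp[cmp$method == "Quantification", ]
  seqRows <- cmp[cmp$method != "Quantification", ]
  qmap <- stats::setNames(quantRows$proportion_pct,
                          paste(quantRows$genus, quantRows$sample))
  fac <- compareToQuantification(
    seqRows$proportion_pct, qmap[paste(seqRows$genus, seqRows$sample)])
  seqRows$factor <- fac$factor
  seqRows$flag <- fac$flag
  art$comparison <- .writeTsv(seqRows,
                              file.path(outDir, "seq_vs_quant.tsv"))

  # (9) HDO fractions and estimated absolute abundances
  db <- readHdoDatabase()
  b16s <- quantResults(quant)
  b16s <- stats::setNames(b16s$copies_per_ml[b16s$target == "B16S"],
                          b16s$sample[b16s$target == "B16S"])
  hdoRows <- list()
  for (m in names(profilesByMethod)) for (s in samples) {
    h <- hdoProportion(profilesByMethod[[m]][[s]], db)
    hdoRows[[paste(m, s)]] <- data.frame(
      sample = s, method = m, hdo_fraction = h$fraction,
      matched_genera = h$matched,
      estimated_copies_per_ml = estimatedHdoAbundance(h$fraction,
                                                      b16s[[s]]))
  }
  art$hdo <- .writeTsv(do.call(rbind, c(hdoRows, make.row.names = FALSE)),
                       file.path(outDir, "hdo_abundance.tsv"))

  # (10) community HDG RPKG profile
  hdg <- stage("hdg", generateHdgCounts(seed = seed))
  rp <- rpkgTable(hdg$counts)
  art$rpkg <- .writeTsv(
    data.frame(sample = rownames(rp$groupSums), rp$groupSums,
               total = as.numeric(rp$totals[rownames(rp$groupSums)]),
               check.names = FALSE),
    file.path(outDir, "hdg_rpkg.tsv"))

  # (11) MAG quality filter, dereplication, organism x cluster presence
  mags <- stage("mags", generateMags(aniThreshold = config$aniThreshold,
                                     seed = seed))
  good <- magQualityFilter(mags$quality)
  membership <- dereplicate(good$mag, mags$ani,
                            threshold = config$aniThreshold)
  presence <- magHdgProfile(mags$hits, membership)
  art$mags <- .writeTsv(
    data.frame(organism = rownames(presence), presence,
               check.names = FALSE),
    file.path(outDir, "mag_hdg_presence.tsv"))
  message(sprintf("stage mags: %d/%d good quality, %d organisms",
                  nrow(good), nrow(mags$quality),
                  length(unique(membership))))

  # (12) depletion metrics
  dep <- depletionMetrics(readConcentrations())
  art$depletion <- .writeTsv(dep, file.path(outDir, "depletion.tsv"))

  # manifest: config hash + per-artifact content hashes
  cfgFile <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfgFile)
  fileHashes <- vapply(art, function(p)
    unname(tools::md5sum(p)), "")
  manifest <- list(
    config_hash = unname(tools::md5sum(cfgFile)),
    seed = seed,
    artifacts = as.list(fileHashes[order(names(fileHashes))]))
  manifest$manifest_hash <- unname(tools::md5sum(
    {tmp <- file.path(outDir, "manifest_body.json")
     jsonlite::write_json(manifest, tmp, auto_unbox = TRUE)
     tmp}))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  unlink(file.path(outDir, "manifest_body.json"))

  invisible(list(artifacts = art, manifest = manifest, truth = truth,
                 profiles = profilesByMethod, harmonized = harm,
                 overlap = overlap, mcia = mc, quant = quant,
                 comparison = seqRows, rpkg = rp,
                 mags = list(good = good, membership = membership,
                             presence = presence),
                 depletion = dep, outDir = outDir))
}

#' Sequencing vs quantification comparison factors
#'
#' Factor = sequencing-based proportion / quantification-derived
#' proportion; factors above 2 are flagged as overestimation, below 0.5
#' as underestimation, and a zero quantification denominator yields an
#' undefined-factor flag.
#'
#' @param seqPct sequencing-based proportions (percent).
#' @param quantPct quantification-derived proportions (percent).
#' @return data.frame with columns factor, flag.
#' @examples
#' compareToQuantification(8.81, 0.25)  # 35.24, overestimation
#' @export
compareToQuantification <- function(seqPct, quantPct) {
  if (length(seqPct) != length(quantPct))
    .stopf("sequencing and quantification vectors must be matched")
  factor <- ifelse(quantPct > 0, seqPct / quantPct, NA_real_)
  flag <- ifelse(is.na(factor) | quantPct == 0, "undefined-factor",
                 ifelse(factor > 2, "overestimation",
                        ifelse(factor < 0.5, "underestimation", "")))
  data.frame(factor = unname(factor), flag = unname(flag),
             stringsAsFactors = FALSE)
}

#' Bundled multi-method genus proportion table
#'
#' The printed comparison of Colwellia, Cycloclasticus and Pseudomonas
#' proportions across five classification methods and qPCR
#' quantification, in long form.
#'
#' @return data.frame: genus, method, sample, proportion_pct (NA where
#'   the sample could not be quantified).
#' @export
readGenusComparisonTable <- function() {
  path <- system.file("extdata", "multimethod_genus_proportions.tsv",
                      package = "taxconsensus", mustWork = TRUE)
  wide <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  samples <- setdiff(names(wide), c("genus", "method"))
  long <- do.call(rbind, lapply(samples, function(s)
    data.frame(genus = wide$genus, method = wide$method, sample = s,
               proportion_pct = wide[[s]], stringsAsFactors = FALSE)))
  long[order(long$genus, long$method, long$sample), ]
}
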