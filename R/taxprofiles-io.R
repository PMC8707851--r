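# Readers for the native report formats of the five classification
# methods. Each reader removes eukaryote and unassignable rows,
# renormalizes proportions over the remaining taxa, and keeps the
# classified fraction from the unclassified row where the format has one.

#' Eukaryotic genus names dropped by the flat-table readers
#'
#' The Kaiju and generic-TSV dialects carry no lineage, so eukaryote
#' removal matches reported names against this (user-extendable) list.
#' @return character vector.
#' @export
defaultEukaryoteGenera <- function() {
  c("Saccharomyces", "Candida", "Thalassiosira", "Phaeodactylum",
    "Emiliania", "Aspergillus", "Micromonas", "Ostreococcus")
}

.emptyProfileStop <- function(path) {
  stop(errorCondition(
    sprintf("no taxa remain after filtering in '%s'", path),
    class = c("emptyProfileError", "taxconsensusError", "error", "condition")))
}

.profileFromCounts <- function(counts, unclassified, sample, method, path) {
  counts <- counts[counts > 0]
  if (!length(counts)) .emptyProfileStop(path)
  if (anyDuplicated(names(counts)))
    counts <- tapply(counts, names(counts), sum)
  cf <- if (is.na(unclassified)) NA_real_ else
    sum(counts) / (sum(counts) + unclassified)
  TaxonomicProfile(sample = sample, method = method,
                   proportions = counts / sum(counts),
                   classifiedFraction = cf)
}

.sampleFromPath <- function(path) {
  b <- sub("\\.[^.]*$", "", basename(path))
  sub("^.*_", "", b)
}

.readKraken2 <- function(path, sample, method, excludeTaxa) {
  lines <- readLines(path)
  unclassified <- 0; domain <- NA_character_
  taxa <- character(0); reads <- numeric(0)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      .stopf("malformed Kraken2 report row at line %d of '%s'", i, path)
    rank <- f[4]; name <- trimws(f[6])
    if (rank == "U") unclassified <- as.numeric(f[2])
    else if (rank == "D") domain <- name
    else if (rank == "G") {
      if (identical(domain, "Eukaryota")) next
      if (name %in% excludeTaxa) next
      taxa <- c(taxa, name); reads <- c(reads, as.numeric(f[3]))
    }
  }
  names(reads) <- taxa
  .profileFromCounts(reads, unclassified, sample, method, path)
}

.readBracken <- function(path, sample, method, excludeTaxa) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) .stopf("cannot parse '%s': %s", path,
                                            conditionMessage(e)))
  need <- c("name", "new_est_reads")
  if (!all(need %in% names(df)))
    .stopf("'%s' lacks Bracken columns %s", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  df <- df[!(df$name %in% excludeTaxa), , drop = FALSE]
  counts <- stats::setNames(as.numeric(df$new_est_reads), df$name)
  .profileFromCounts(counts, NA_real_, sample, method, path)
}

.readKaiju <- function(path, sample, method, excludeTaxa) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reads", "taxon_name")
  if (!all(need %in% names(df)))
    .stopf("'%s' lacks kaiju2table columns %s", path,
           paste(setdiff(need, names(df)), collapse = ", "))
  drop <- df$taxon_name == "unclassified" |
    grepl("^cannot be assigned", df$taxon_name) |
    grepl("^Viruses", df$taxon_name)
  unclassified <- sum(as.numeric(df$reads[drop]))
  keep <- df[!drop & !(df$taxon_name %in% excludeTaxa), , drop = FALSE]
  counts <- stats::setNames(as.numeric(keep$reads), keep$taxon_name)
  .profileFromCounts(counts, unclassified, sample, method, path)
}

.stripConfidence <- function(x) gsub("\\([0-9.]+\\)", "", x)

.readAmplicon <- function(path, taxonomyPath, method, excludeTaxa) {
  if (is.null(taxonomyPath))
    .stopf("amplicon format needs both a shared file and taxonomyPath")
  shared <- utils::read.delim(path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  tax <- utils::read.delim(taxonomyPath, stringsAsFactors = FALSE)
  if (!all(c("Group") %in% names(shared)) || !all(c("OTU", "Taxonomy") %in% names(tax)))
    .stopf("'%s'/'%s' are not a mothur shared/taxonomy pair", path,
           taxonomyPath)
  lineage <- strsplit(.stripConfidence(tax$Taxonomy), ";", fixed = TRUE)
  kingdom <- vapply(lineage, function(l) if (length(l)) l[[1]] else "", "")
  genus <- vapply(lineage, function(l) {
    l <- trimws(l[nzchar(trimws(l))])
    if (!length(l)) return(NA_character_)
    l[[length(l)]]
  }, "")
  bad <- kingdom %in% c("Eukaryota", "unknown") | is.na(genus) |
    grepl("unclassified|unknown|uncultured", genus, ignore.case = TRUE) |
    genus %in% excludeTaxa
  otuGenus <- stats::setNames(genus, tax$OTU)
  otuGenus[bad[match(names(otuGenus), tax$OTU)]] <- NA_character_
  otuCols <- setdiff(names(shared), c("label", "Group", "numOtus"))
  out <- lapply(seq_len(nrow(shared)), function(i) {
    cnt <- as.numeric(shared[i, otuCols])
    g <- otuGenus[otuCols]
    ok <- !is.na(g) & cnt > 0
    counts <- tapply(cnt[ok], g[ok], sum)
    .profileFromCounts(counts, NA_real_, shared$Group[i], method, path)
  })
  names(out) <- shared$Group
  out
}

.readGenericTsv <- function(path, method, excludeTaxa) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  valueCol <- intersect(c("count", "proportion"), names(df))[1]
  if (!all(c("sample", "taxon") %in% names(df)) || is.na(valueCol))
    .stopf("'%s' needs columns sample, taxon and count or proportion", path)
  df <- df[!(df$taxon %in% excludeTaxa), , drop = FALSE]
  out <- lapply(split(df, df$sample), function(d)
    .profileFromCounts(stats::setNames(as.numeric(d[[valueCol]]), d$taxon),
                       NA_real_, d$sample[1], method, path))
  out[order(names(out))]
}

#' Read a classifier report into TaxonomicProfile objects
#'
#' Supported dialects: Kraken2 report (6 tab-separated columns, names
#' indented, domain rows tracked so Eukaryota subtrees are dropped),
#' Bracken genus table, kaiju2table summary, mothur-style shared/taxonomy
#' pair (confidence suffixes stripped, lineages split on ';'), and a
#' generic long TSV (sample, taxon, count|proportion). Eukaryote and
#' unassignable rows are removed and proportions renormalized; the
#' classified fraction is retained where the format reports unclassified
#' reads.
#'
#' @param path report path (the shared file for amplicon).
#' @param format one of \code{"kraken2"}, \code{"bracken"},
#'   \code{"kaiju"}, \code{"amplicon"}, \code{"generic_tsv"}.
#' @param level taxonomic level of the returned profile; phylum-level
#'   profiles are aggregated through \code{phylumMap}.
#' @param sample sample ID (single-sample formats; default parsed from
#'   the file name).
#' @param method method label (default from format).
#' @param taxonomyPath mothur taxonomy file (amplicon only).
#' @param phylumMap named genus -> phylum/class vector, required for
#'   \code{level = "phylum_with_proteo_classes"}.
#' @param excludeTaxa taxa dropped as eukaryotic.
#' @return a \linkS4class{TaxonomicProfile}, or a named list of them for
#'   multi-sample formats. Signals an error of class
#'   \code{emptyProfileError} when nothing remains after filtering.
#' @export
readReport <- function(path, format = c("kraken2", "bracken", "kaiju",
                                        "amplicon", "generic_tsv"),
                       level = "genus", sample = NULL, method = NULL,
                       taxonomyPath = NULL, phylumMap = NULL,
                       excludeTaxa = defaultEukaryoteGenera()) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: '%s'", path)
  if (is.null(method))
    method <- c(kraken2 = "Kraken2", bracken = "Bracken", kaiju = "Kaiju",
                amplicon = "Amplicon", generic_tsv = "Generic")[[format]]
  if (is.null(sample)) sample <- .sampleFromPath(path)
  res <- switch(format,
    kraken2 = .readKraken2(path, sample, method, excludeTaxa),
    bracken = .readBracken(path, sample, method, excludeTaxa),
    kaiju = .readKaiju(path, sample, method, excludeTaxa),
    amplicon = .readAmplicon(path, taxonomyPath, method, excludeTaxa),
    generic_tsv = .readGenericTsv(path, method, excludeTaxa))
  if (level == "phylum_with_proteo_classes") {
    if (is.null(phylumMap))
      .stopf("phylum-level profiles need a phylumMap (genus -> phylum)")
    res <- if (is(res, "TaxonomicProfile")) aggregateToPhylum(res, phylumMap)
    else lapply(res, aggregateToPhylum, phylumMap = phylumMap)
  }
  res
}

#' Aggregate a genus-level profile to phyla (Proteobacteria as classes)
#'
#' Genera missing from the map are pooled under "unknown_phylum".
#'
#' @param profile a genus-level \linkS4class{TaxonomicProfile}.
#' @param phylumMap named genus -> phylum/class vector.
#' @return a phylum-level \linkS4class{TaxonomicProfile}.
#' @export
aggregateToPhylum <- function(profile, phylumMap) {
  p <- taxonProportions(profile)
  ph <- phylumMap[names(p)]
  ph[is.na(ph)] <- "unknown_phylum"
  agg <- tapply(p, ph, sum)
  TaxonomicProfile(sample = sampleName(profile),
                   method = methodName(profile),
                   proportions = agg[order(names(agg))],
                   level = "phylum_with_proteo_classes",
                   classifiedFraction = classifiedFraction(profile))
}

#' Write harmonized profiles as long-form TSV
#'
#' @param harmonized result of [harmonizeProfiles()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeHarmonizedProfiles <- function(harmonized, path) {
  m <- harmonized$matrix
  info <- harmonized$info
  long <- do.call(rbind, lapply(seq_len(nrow(m)), function(i)
    data.frame(sample = info$sample[i], method = info$method[i],
               level = info$level[i], taxon = colnames(m),
               proportion = m[i, ],
               classified_fraction = info$classifiedFraction[i])))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
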