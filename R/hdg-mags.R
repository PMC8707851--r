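# Hydrocarbon-degradation-gene (HDG) profiling: RPKG normalization for
# communities, cluster-presence calls and quality filtering for MAGs,
# and ANI-based dereplication into organisms.

#' Read HDG gene/cluster definitions
#'
#' TSV with one row per gene: gene symbol, cluster ID (multi-component
#' clusters like pmoABC list each component gene on its own row under
#' the shared cluster ID; standalone genes are their own cluster),
#' compound group (aliphatic | MAH | PAH | various) and gene length in
#' bp. The bundled table covers the clusters prominent in marine oil
#' degradation; the full gene panel is pluggable through `path`.
#'
#' @param path TSV path; default the bundled definitions.
#' @return data.frame with columns gene, cluster, group, length_bp.
#' @export
readGeneDefs <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hdg_gene_defs.tsv",
                        package = "taxconsensus", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "cluster", "group", "length_bp")
  if (!all(need %in% names(df)))
    .stopf("gene definitions need columns %s", paste(need, collapse = ", "))
  if (!all(df$group %in% c("aliphatic", "MAH", "PAH", "various")))
    .stopf("group must be one of aliphatic, MAH, PAH, various")
  if (any(df$length_bp <= 0)) .stopf("gene lengths must be > 0")
  df
}

#' Reads per kilobase per genome equivalent (RPKG)
#'
#' RPKG = reads / (gene length in kb x genome equivalents): a
#' sequencing-depth- and genome-size-normalized gene abundance, linear
#' in reads and inverse-linear in genome equivalents.
#'
#' @param reads read counts (>= 0).
#' @param lengthBp gene lengths in bp (> 0).
#' @param genomeEquivalents genome equivalents of the sample (> 0).
#' @return numeric RPKG values.
#' @examples
#' rpkg(100, 1000, 10)  # 10
#' @export
rpkg <- function(reads, lengthBp, genomeEquivalents) {
  if (any(!is.finite(lengthBp)) || any(lengthBp <= 0))
    .stopf("gene length must be > 0")
  if (any(!is.finite(genomeEquivalents)) || any(genomeEquivalents <= 0))
    .stopf("genome equivalents must be > 0")
  reads / ((lengthBp / 1000) * genomeEquivalents)
}

#' Per-sample RPKG profile with compound-group sums
#'
#' @param counts data.frame (sample, gene, reads, gene_length_bp,
#'   genome_equivalents); lengths missing from the table are taken from
#'   `geneDefs`, and a counted gene with no known length is an error.
#' @param geneDefs gene definitions, see [readGeneDefs()].
#' @return list with \code{perGene} (long data.frame sample, gene, group,
#'   rpkg), \code{groupSums} (sample x group matrix) and \code{totals}
#'   (named per-sample summed RPKG).
#' @export
rpkgTable <- function(counts, geneDefs = readGeneDefs()) {
  lenMap <- stats::setNames(geneDefs$length_bp, geneDefs$gene)
  grpMap <- stats::setNames(geneDefs$group, geneDefs$gene)
  len <- if ("gene_length_bp" %in% names(counts)) counts$gene_length_bp
  else lenMap[counts$gene]
  if (any(is.na(len)))
    .stopf("missing gene length for: %s",
           paste(unique(counts$gene[is.na(len)]), collapse = ", "))
  perGene <- data.frame(
    sample = counts$sample, gene = counts$gene,
    group = ifelse(is.na(grpMap[counts$gene]), "various",
                   grpMap[counts$gene]),
    rpkg = rpkg(counts$reads, len, counts$genome_equivalents),
    stringsAsFactors = FALSE)
  groupSums <- tapply(perGene$rpkg, list(perGene$sample, perGene$group),
                      sum, default = 0)
  totals <- tapply(perGene$rpkg, perGene$sample, sum)
  list(perGene = perGene, groupSums = groupSums,
       totals = totals[unique(perGene$sample)])
}

#' Is a gene cluster present in a MAG?
#'
#' A cluster counts as present when strictly more than half of its
#' component genes are registered in the MAG (exactly half is absent).
#'
#' @param magGenes character vector of genes registered in the MAG.
#' @param cluster cluster ID.
#' @param geneDefs gene definitions, see [readGeneDefs()].
#' @return logical.
#' @examples
#' defs <- data.frame(gene = c("pmoA", "pmoB", "pmoC"),
#'                    cluster = "pmoABC", group = "aliphatic",
#'                    length_bp = 750)
#' clusterPresence(c("pmoA", "pmoB"), "pmoABC", defs)  # TRUE (2/3)
#' @export
clusterPresence <- function(magGenes, cluster, geneDefs = readGeneDefs()) {
  comp <- geneDefs$gene[geneDefs$cluster == cluster]
  if (!length(comp)) .stopf("unknown cluster '%s'", cluster)
  sum(comp %in% magGenes) / length(comp) > 0.5
}

#' Filter MAGs to the good-quality subset
#'
#' Keeps MAGs with completeness strictly above 50\% and contamination
#' strictly below 10\% (both boundaries rejected).
#'
#' @param records data.frame with columns mag, completeness,
#'   contamination.
#' @return the good-quality subset of `records`.
#' @export
magQualityFilter <- function(records) {
  need <- c("mag", "completeness", "contamination")
  if (!all(need %in% names(records)))
    .stopf("MAG records need columns %s", paste(need, collapse = ", "))
  if (any(records$completeness < 0 | records$completeness > 100))
    .stopf("completeness outside [0, 100]")
  records[records$completeness > 50 & records$contamination < 10, ,
          drop = FALSE]
}

#' Dereplicate MAGs into organisms by ANI
#'
#' MAG pairs with average nucleotide identity at or above the threshold
#' are the same organism; organisms are the single-linkage closure
#' (connected components) of that relation. Missing pairs count as below
#' threshold.
#'
#' @param mags character vector of MAG IDs.
#' @param ani data.frame (mag_a, mag_b, ani in [0, 100]); must be
#'   symmetric where both directions are given.
#' @param threshold same-organism threshold, in (0, 100]; default 95
#'   (inclusive).
#' @return named integer vector: MAG -> organism cluster ID; clusters
#'   are disjoint and cover the input set.
#' @export
dereplicate <- function(mags, ani, threshold = 95) {
  if (threshold <= 0 || threshold > 100)
    .stopf("threshold outside (0, 100]")
  if (any(ani$ani < 0 | ani$ani > 100)) .stopf("ANI outside [0, 100]")
  key <- paste(pmin(ani$mag_a, ani$mag_b), pmax(ani$mag_a, ani$mag_b))
  for (k in unique(key[duplicated(key)])) {
    v <- ani$ani[key == k]
    if (max(v) - min(v) > 1e-6)
      .stopf("asymmetric ANI for pair %s", k)
  }
  ani <- ani[ani$mag_a %in% mags & ani$mag_b %in% mags, , drop = FALSE]
  edges <- ani[ani$ani >= threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("mag_a", "mag_b")], directed = FALSE,
    vertices = data.frame(name = mags))
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp[mags]), mags)
}

#' Organism x cluster HDG presence matrix with partial marks
#'
#' Per organism lane (a dereplication cluster of MAGs): "full" when
#' every member MAG carries the gene cluster, "partial" when only some
#' do, "none" otherwise.
#'
#' @param hits data.frame (mag, gene) of registered gene hits.
#' @param membership named MAG -> organism vector from [dereplicate()].
#' @param geneDefs gene definitions, see [readGeneDefs()].
#' @return character matrix, organisms x clusters, values
#'   "full"/"partial"/"none".
#' @export
magHdgProfile <- function(hits, membership, geneDefs = readGeneDefs()) {
  orgs <- sort(unique(membership))
  clusters <- unique(geneDefs$cluster)
  out <- matrix("none", length(orgs), length(clusters),
                dimnames = list(paste0("organism", orgs), clusters))
  for (oi in seq_along(orgs)) {
    members <- names(membership)[membership == orgs[oi]]
    for (cl in clusters) {
      pres <- vapply(members, function(m)
        clusterPresence(hits$gene[hits$mag == m], cl, geneDefs), TRUE)
      out[oi, cl] <- if (all(pres)) "full" else if (any(pres)) "partial"
      else "none"
    }
  }
  out
}
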