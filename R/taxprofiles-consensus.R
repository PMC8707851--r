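# Rank-consensus, set-overlap, compositional-transform and clustering
# procedures over harmonized multi-method taxonomic profiles.

#' Harmonize profiles from several methods onto a shared taxon set
#'
#' Taxa are matched by exact name after applying an optional synonym
#' table (e.g. mapping SILVA's unresolved Proteobacterial classes onto a
#' shared label); taxa absent from a method's output hold proportion 0
#' and can be flagged as absent from that method's reference database.
#'
#' @param profiles list of \linkS4class{TaxonomicProfile}, all at the
#'   same level.
#' @param synonyms optional data.frame with columns \code{from},
#'   \code{to}; a name mapped to two different targets is an error.
#' @param absentFromDb optional named list, method -> genera known absent
#'   from that method's reference database.
#' @return list with \code{matrix} ((sample, method) rows x union-taxa
#'   columns), \code{info} (sample, method, level, classifiedFraction per
#'   row) and \code{absent} (the absent-from-database flags restricted to
#'   the union taxa).
#' @export
harmonizeProfiles <- function(profiles, synonyms = NULL,
                              absentFromDb = NULL) {
  stopifnot(length(profiles) >= 1)
  lev <- unique(vapply(profiles, profileLevel, ""))
  if (length(lev) != 1L)
    .stopf("all profiles must be at the same level (got: %s)",
           paste(lev, collapse = ", "))
  mapName <- identity
  if (!is.null(synonyms)) {
    stopifnot(all(c("from", "to") %in% names(synonyms)))
    dup <- synonyms$from[duplicated(synonyms$from)]
    conflict <- unique(dup[vapply(dup, function(f)
      length(unique(synonyms$to[synonyms$from == f])) > 1, TRUE)])
    if (length(conflict))
      .stopf("conflicting synonym mapping for: %s",
             paste(conflict, collapse = ", "))
    syn <- stats::setNames(synonyms$to, synonyms$from)
    mapName <- function(x) ifelse(x %in% names(syn), syn[x], x)
  }
  mapped <- lapply(profiles, function(pr) {
    p <- taxonProportions(pr)
    nm <- unname(mapName(names(p)))
    tapply(p, nm, sum)
  })
  taxa <- sort(unique(unlist(lapply(mapped, names))))
  m <- matrix(0, nrow = length(profiles), ncol = length(taxa),
              dimnames = list(NULL, taxa))
  for (i in seq_along(mapped)) m[i, names(mapped[[i]])] <- mapped[[i]]
  info <- data.frame(
    sample = vapply(profiles, sampleName, ""),
    method = vapply(profiles, methodName, ""),
    level = lev,
    classifiedFraction = vapply(profiles, classifiedFraction, 0),
    stringsAsFactors = FALSE)
  rownames(m) <- paste(info$sample, info$method, sep = "|")
  absent <- NULL
  if (!is.null(absentFromDb))
    absent <- lapply(absentFromDb, intersect, y = taxa)
  list(matrix = m, info = info, absent = absent)
}

#' Rank the top taxa of a profile
#'
#' The n most abundant taxa receive distinct integer ranks n..1 (highest
#' value = most abundant); all other taxa receive 0 ("not prominent").
#' Ties in proportion are broken lexicographically by taxon name.
#'
#' @param profile a \linkS4class{TaxonomicProfile} or named numeric
#'   vector of proportions.
#' @param n top-list size (default 20, the phylum-rank convention).
#' @return named integer vector over the profile's taxa.
#' @examples
#' rankTaxa(c(A = 0.5, B = 0.3, C = 0.2), n = 3)  # A=3 B=2 C=1
#' @export
rankTaxa <- function(profile, n = 20) {
  if (n < 1) .stopf("top-list size must be >= 1")
  p <- if (is(profile, "TaxonomicProfile")) taxonProportions(profile)
  else profile
  if (!length(p)) return(integer(0))
  ord <- order(-p, names(p))
  ranks <- stats::setNames(rep(0L, length(p)), names(p))
  top <- ord[seq_len(min(n, length(p)))]
  ranks[top] <- as.integer(seq(n, by = -1L, length.out = length(top)))
  ranks
}

#' Average rank over methods
#'
#' Arithmetic mean of per-method rank values for each taxon, counting a
#' taxon missing from a method's top list as rank 0.
#'
#' @param ranks a named list of rank vectors (one per method, as from
#'   [rankTaxa()]) or a taxa x methods matrix.
#' @return named numeric vector of average ranks over the union taxa.
#' @examples
#' averageRanks(list(a = c(Firmicutes = 18), b = c(Firmicutes = 13)))
#' @export
averageRanks <- function(ranks) {
  if (is.matrix(ranks)) return(rowMeans(ranks))
  if (length(ranks) < 1) .stopf("need at least one method")
  taxa <- sort(unique(unlist(lapply(ranks, names))))
  m <- vapply(ranks, function(r) {
    out <- stats::setNames(rep(0, length(taxa)), taxa)
    out[names(r)] <- r
    out
  }, numeric(length(taxa)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(taxa),
                                   dimnames = list(taxa, names(ranks)))
  rowMeans(m)
}

#' Pooled top-n taxa of one method across samples
#'
#' Each taxon is scored by its maximum (default) or mean proportion over
#' the method's samples, and the n best scores win; ties break
#' lexicographically. Maximum pooling preserves treatment-specific
#' dominants that peak in a single sample.
#'
#' @param profiles list of \linkS4class{TaxonomicProfile} of one method.
#' @param n pooled top-list size (default 50, the genus convention).
#' @param stat pooling statistic, \code{"max"} or \code{"mean"}.
#' @return character vector of taxa (length <= n).
#' @export
topGenera <- function(profiles, n = 50, stat = c("max", "mean")) {
  stat <- match.arg(stat)
  taxa <- sort(unique(unlist(lapply(profiles, function(p)
    names(taxonProportions(p))))))
  score <- vapply(taxa, function(tx) {
    v <- vapply(profiles, function(p) {
      pp <- taxonProportions(p)
      if (tx %in% names(pp)) pp[[tx]] else 0
    }, 0)
    if (stat == "max") max(v) else mean(v)
  }, 0)
  taxa[order(-score, taxa)][seq_len(min(n, length(taxa)))]
}

#' Overlap region sizes of per-method taxon sets (Venn structure)
#'
#' For K methods, returns the size of every region of the Venn diagram:
#' each taxon in the union is assigned to the unique region given by
#' exactly which methods report it. Region sizes are non-negative and sum
#' to the union size.
#'
#' @param sets named list (>= 2) of character vectors, one per method.
#' @return named integer vector over all non-empty method subsets, names
#'   like \code{"Kaiju&Kraken2"}; attribute \code{"union"} holds the
#'   union size.
#' @export
topSetOverlap <- function(sets) {
  if (length(sets) < 2) .stopf("need >= 2 methods")
  methods <- names(sets)
  u <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(u))
  K <- length(sets)
  regions <- integer(0)
  for (mask in seq_len(2^K - 1)) {
    inSet <- as.logical(bitwAnd(mask, 2^(seq_len(K) - 1)))
    nm <- paste(methods[inSet], collapse = "&")
    cnt <- sum(apply(membership, 1, function(row) all(row == inSet)))
    regions[nm] <- cnt
  }
  attr(regions, "union") <- length(u)
  regions
}

#' Centered log-ratio (clr) transform
#'
#' Per row (sample): \eqn{clr(p)_j = \log((p_j+\delta)/g)} with g the
#' geometric mean of the shifted parts, so each row sums to zero. The
#' default pseudocount is half the smallest nonzero proportion of the
#' matrix (standard zero replacement).
#'
#' @param mat samples x taxa proportion matrix (rows need not be
#'   renormalized after the shift; clr is invariant to scaling).
#' @param pseudocount zero-replacement offset; must be > 0 when the
#'   matrix contains zeros.
#' @return matrix of the same shape; rows sum to 0 (within 1e-9).
#' @export
clrTransform <- function(mat, pseudocount = NULL) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) .stopf("proportions must be >= 0")
  if (is.null(pseudocount)) {
    nz <- mat[mat > 0]
    pseudocount <- if (any(mat == 0)) min(nz) / 2 else 0
  }
  if (pseudocount < 0 || (pseudocount == 0 && any(mat == 0)))
    .stopf("pseudocount must be > 0 when zeros are present")
  lm <- log(mat + pseudocount)
  sweep(lm, 1, rowMeans(lm), "-")
}

#' Ward clustering of samples
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage
#' (the variance-minimizing criterion on unsquared distances,
#' \code{hclust} method \code{"ward.D2"}).
#'
#' @param mat samples x variables matrix (>= 2 rows, finite values).
#' @return an object of class \code{hclust}; merge heights are
#'   non-decreasing.
#' @export
wardCluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) .stopf("need >= 2 rows to cluster")
  if (any(!is.finite(mat))) .stopf("non-finite values in clustering input")
  stats::hclust(stats::dist(mat), method = "ward.D2")
}
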