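# Shared fixtures: tiny communities, identity bias, and rank-error
# helpers used across test files.

tinyCatalog <- function(genera = c("Pseudomonas", "Colwellia", "Ulvibacter",
                                   "Hyphomonas"),
                        phyla = c("Gammaproteobacteria",
                                  "Gammaproteobacteria", "Bacteroidetes",
                                  "Alphaproteobacteria")) {
  data.frame(genus = genera, phylum = phyla,
             archaeal = FALSE,
             hdo = genera %in% readHdoDatabase()$genus,
             stringsAsFactors = FALSE)
}

identityBias <- function(depth = 1e5, method = "Ideal") {
  biasModel(method, classifiedFraction = 1, depth = depth)
}

# mean absolute rank error between two rank vectors over their union
rankError <- function(obs, truth) {
  taxa <- union(names(obs), names(truth))
  o <- stats::setNames(rep(0, length(taxa)), taxa); o[names(obs)] <- obs
  t <- stats::setNames(rep(0, length(taxa)), taxa); t[names(truth)] <- truth
  mean(abs(o - t))
}

# brute-force Venn region sizes by power-set enumeration (independent of
# topSetOverlap's implementation)
bruteRegions <- function(sets) {
  methods <- names(sets)
  u <- unique(unlist(sets))
  out <- integer(0)
  for (mask in seq_len(2^length(sets) - 1)) {
    inSet <- as.logical(bitwAnd(mask, 2^(seq_along(sets) - 1)))
    cnt <- sum(vapply(u, function(tx)
      all(vapply(seq_along(sets), function(k)
        (tx %in% sets[[k]]) == inSet[k], TRUE)), TRUE))
    out[paste(methods[inSet], collapse = "&")] <- cnt
  }
  out
}
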