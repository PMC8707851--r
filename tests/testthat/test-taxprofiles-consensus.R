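toyProfile <- function(p, sample = "s1", method = "m1")
  TaxonomicProfile(sample, method, p)

test_that("harmonization aligns taxa, applies synonyms, flags conflicts", {
  a <- toyProfile(c(Alpha = 0.6, Beta = 0.4), method = "m1")
  b <- toyProfile(c(Gamma = 1), method = "m2")
  h <- harmonizeProfiles(list(a, b))
  expect_equal(colnames(h$matrix), c("Alpha", "Beta", "Gamma"))
  expect_equal(unname(h$matrix[2, ]), c(0, 0, 1))
  expect_equal(ncol(h$matrix), 3)  # |A union B|

  syn <- data.frame(from = "Betaproteobacteria",
                    to = "Proteobacteria_unresolved")
  c1 <- toyProfile(c(Betaproteobacteria = 0.5, Alpha = 0.5), method = "m3")
  h2 <- harmonizeProfiles(list(c1), synonyms = syn)
  expect_true("Proteobacteria_unresolved" %in% colnames(h2$matrix))
  expect_false("Betaproteobacteria" %in% colnames(h2$matrix))

  badSyn <- data.frame(from = c("X", "X"), to = c("A", "B"))
  expect_error(harmonizeProfiles(list(a), synonyms = badSyn),
               "conflicting synonym")
  phyl <- aggregateToPhylum(a, c(Alpha = "P1", Beta = "P2"))
  expect_error(harmonizeProfiles(list(a, phyl)), "same level")
})

test_that("rankTaxa assigns descending ranks with lexicographic ties", {
  expect_equal(rankTaxa(c(A = 0.5, B = 0.3, C = 0.2), n = 3),
               c(A = 3L, B = 2L, C = 1L))
  expect_equal(rankTaxa(c(A = 0.4, B = 0.4, C = 0.2), n = 3),
               c(A = 3L, B = 2L, C = 1L))
  p25 <- stats::setNames(25:1 / sum(25:1), sprintf("t%02d", 1:25))
  r <- rankTaxa(p25, n = 20)
  expect_equal(sum(r == 0), 5)
  expect_setequal(r[r > 0], 1:20)
})

test_that("top-n ranks are a permutation of n..1 on random profiles", {
  set.seed(42)
  for (i in 1:10) {
    k <- sample(5:40, 1)
    p <- stats::setNames(stats::runif(k), paste0("g", seq_len(k)))
    p <- p / sum(p)
    n <- sample(1:25, 1)
    r <- rankTaxa(p, n)
    # most abundant always holds rank n; k < n truncates from below
    expect_setequal(r[r > 0], seq(n, by = -1,
                                  length.out = min(n, k)))
    # top-ranked taxon is the most abundant
    expect_equal(names(which.max(r)), names(which.max(p)))
  }
})

test_that("average ranks are the arithmetic mean including zeros", {
  ranks <- list(Bracken = c(Firmicutes = 18), Kraken2 = c(Firmicutes = 18),
                Kaiju = c(Firmicutes = 13), Amplicon = c(Firmicutes = 8),
                KaijuMAR = c(Firmicutes = 6))
  expect_equal(unname(averageRanks(ranks)[["Firmicutes"]]), 12.6)
  expect_equal(unname(averageRanks(list(a = c(X = 7), b = c(X = 7)))[["X"]]), 7)
  expect_equal(unname(averageRanks(list(a = c(X = 20), b = c(Y = 1)))[["X"]]), 10)
})

test_that("with identity bias the consensus ordering matches the truth", {
  # well-separated geometric abundances so the ordering is identifiable
  catalog <- data.frame(genus = sprintf("g%02d", 1:15), phylum = "P",
                        archaeal = FALSE, hdo = FALSE)
  tr <- generateTruth(design = data.frame(sample = "SW0",
                                          treatment = "SW", time = 0,
                                          replicate = 1),
                      seed = 8, genusCatalog = catalog, noise = FALSE)
  tr@abundance[, 1] <- 1e6 * 1.5^(15:1)
  ranksTruth <- rankTaxa(trueProportions(tr)[, "SW0"], 10)
  ranks <- lapply(1:5, function(i) {
    obs <- observeWithClassifier(tr, identityBias(1e6, paste0("m", i)),
                                 seed = i)
    rankTaxa(observationProfiles(obs)$SW0, 10)
  })
  avg <- averageRanks(stats::setNames(ranks, paste0("m", 1:5)))
  topTruth <- names(sort(ranksTruth[ranksTruth > 0], decreasing = TRUE))
  topAvg <- names(sort(avg, decreasing = TRUE))[seq_along(topTruth)]
  expect_equal(topAvg, topTruth)
})

test_that("overlap regions match brute-force power-set enumeration", {
  same <- list(a = c("x", "y"), b = c("x", "y"))
  r <- topSetOverlap(same)
  expect_equal(unname(r[["a&b"]]), 2)
  expect_equal(sum(r), attr(r, "union"))

  disjoint <- list(a = c("x"), b = c("y"), c = c("z"))
  expect_equal(unname(topSetOverlap(disjoint)[["a&b&c"]]), 0)

  set.seed(1)
  sets <- list(a = sample(letters, 12), b = sample(letters, 8),
               c = sample(letters, 15))
  got <- topSetOverlap(sets)
  want <- bruteRegions(sets)
  expect_equal(got[names(want)], want, ignore_attr = TRUE)
  expect_equal(sum(got), attr(got, "union"))
  expect_error(topSetOverlap(list(a = "x")), ">= 2")
})

test_that("pooled top lists use the configured statistic", {
  profs <- list(
    toyProfile(c(A = 0.9, B = 0.05, C = 0.05), sample = "s1"),
    toyProfile(c(A = 0.05, B = 0.05, C = 0.9), sample = "s2"))
  expect_equal(topGenera(profs, n = 2, stat = "max"), c("A", "C"))
  expect_equal(topGenera(profs, n = 1, stat = "mean"), "A")
})

test_that("clr transform matches the closed form and sums to zero", {
  u <- matrix(1 / 4, 2, 4)
  expect_true(all(abs(clrTransform(u)) < 1e-12))
  x <- matrix(c(0.5, 0.25, 0.25), 1)
  got <- clrTransform(x, pseudocount = 0)
  expect_equal(round(as.numeric(got), 3), c(0.462, -0.231, -0.231))
  set.seed(3)
  m <- matrix(stats::runif(60), 6)
  m <- m / rowSums(m)
  m[1, 1] <- 0
  m[1, ] <- m[1, ] / sum(m[1, ])
  z <- clrTransform(m)
  expect_true(all(abs(rowSums(z)) < 1e-9))
  expect_error(clrTransform(m, pseudocount = 0), "pseudocount")
})

test_that("Ward clustering has monotone heights and recovers plantings", {
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5))
  hc <- wardCluster(m)
  expect_equal(hc$height[1], 0)

  planted <- rbind(p1 = c(0, 0.1), p2 = c(0.1, 0), q1 = c(9, 9.1),
                   q2 = c(9.1, 9))
  hc2 <- wardCluster(planted)
  top <- stats::cutree(hc2, k = 2)
  expect_equal(unname(top), c(1, 1, 2, 2))
  # brute-force: of all 2-partitions, the planted one minimizes
  # within-cluster variance
  parts <- utils::combn(4, 2, simplify = FALSE)
  wss <- vapply(parts, function(idx) {
    a <- planted[idx, , drop = FALSE]; b <- planted[-idx, , drop = FALSE]
    sum(scale(a, scale = FALSE)^2) + sum(scale(b, scale = FALSE)^2)
  }, 0)
  expect_equal(sort(parts[[which.min(wss)]]), unname(which(top == 1)))

  set.seed(4)
  r <- matrix(stats::rnorm(50), 10)
  expect_true(all(diff(wardCluster(r)$height) >= -1e-12))
  r[1, 1] <- NA
  expect_error(wardCluster(r), "finite")
  expect_error(wardCluster(r[1, , drop = FALSE]), "2 rows")
})
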