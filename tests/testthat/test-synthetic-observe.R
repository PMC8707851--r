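test_that("identity bias reproduces the true proportions at large depth", {
  tr <- generateTruth(seed = 5)
  obs <- observeWithClassifier(tr, identityBias(depth = 1e6), seed = 1)
  p <- trueProportions(tr)
  for (s in c("SW0", "SWOB8.1")) {
    got <- taxonProportions(observationProfiles(obs)[[s]])
    expect_lt(max(abs(got[rownames(p)] - p[, s])), 0.01)
  }
})

test_that("KL divergence to the truth vanishes at depth 1e6", {
  tr <- generateTruth(seed = 5)
  p <- trueProportions(tr)[, "SW0"]
  for (sd in 1:3) {
    obs <- observeWithClassifier(tr, identityBias(depth = 1e6), seed = sd)
    q <- taxonProportions(observationProfiles(obs)$SW0)[names(p)]
    keep <- q > 0
    kl <- sum(p[keep] * log(p[keep] / q[keep]))
    expect_lt(kl, 0.01)
  }
})

test_that("database-missing genera are reported as exactly zero", {
  tr <- generateTruth(seed = 1)
  b <- biasModel("drop", dbMissing = "Pseudomonas", depth = 1e4)
  obs <- observeWithClassifier(tr, b, seed = 1)
  for (s in names(obs$samples))
    expect_identical(unname(obs$samples[[s]]$counts[["Pseudomonas"]]), 0)
})

test_that("oversampling renormalizes as expected on a two-genus community", {
  catalog <- tinyCatalog(c("Pseudomonas", "Colwellia"),
                         c("Gammaproteobacteria", "Gammaproteobacteria"))
  params <- defaultTruthParams()
  params$blooms <- list()
  design <- data.frame(sample = "SW0", treatment = "SW", time = 0,
                       replicate = 1)
  # force an exact 50/50 community
  tr <- generateTruth(design, params, seed = 1, genusCatalog = catalog,
                      noise = FALSE)
  tr@abundance[] <- c(5e5, 5e5)
  b <- biasModel("over", oversample = c(Pseudomonas = 5), depth = 1e6)
  obs <- observeWithClassifier(tr, b, seed = 2)
  prop <- taxonProportions(observationProfiles(obs)$SW0)
  expect_equal(unname(prop[["Pseudomonas"]]), 5 / 6, tolerance = 0.005)
})

test_that("the unclassified fraction and false positives behave as configured", {
  tr <- generateTruth(seed = 2)
  b <- biasModel("frac", classifiedFraction = 0.4, falsePositiveRate = 5,
                 depth = 1e5)
  obs <- observeWithClassifier(tr, b, seed = 3)
  s <- obs$samples$SW0
  expect_equal(s$unclassified, 6e4)
  fp <- intersect(names(s$counts), falsePositiveCatalog())
  expect_true(all(s$counts[fp] %in% 1:3))
  cf <- classifiedFraction(observationProfiles(obs)$SW0)
  expect_equal(cf, 0.4, tolerance = 0.001)
})

test_that("observation is deterministic and fails on empty communities", {
  tr <- generateTruth(seed = 2)
  b <- defaultBiasModels(genusInfo(tr))$Kraken2
  o1 <- observeWithClassifier(tr, b, seed = 9)
  o2 <- observeWithClassifier(tr, b, seed = 9)
  expect_identical(o1, o2)
  allGone <- biasModel("gone",
                       dbMissing = genusInfo(tr)$genus, depth = 100)
  expect_error(observeWithClassifier(tr, allGone, seed = 1),
               "empty community")
})
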