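writeLinesTmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".kreport",
                             .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("Kraken2 reports parse with renormalization and classified fraction", {
  p <- writeLinesTmp(c(
    "50.00\t100\t100\tU\t0\tunclassified",
    "50.00\t100\t0\tR\t1\troot",
    "50.00\t100\t0\tD\t2\t  Bacteria",
    "30.00\t60\t60\tG\t1001\t    Alpha",
    "15.00\t30\t30\tG\t1002\t    Beta",
    "5.00\t10\t10\tG\t1003\t    Gamma"))
  pr <- readReport(p, "kraken2", sample = "s1")
  expect_equal(unname(taxonProportions(pr)[c("Alpha", "Beta", "Gamma")]),
               c(0.6, 0.3, 0.1))
  expect_equal(classifiedFraction(pr), 0.5)
})

test_that("Eukaryota subtrees are dropped from Kraken2 reports", {
  p <- writeLinesTmp(c(
    "0.00\t0\t0\tU\t0\tunclassified",
    "100.00\t120\t0\tR\t1\troot",
    "83.33\t100\t0\tD\t2\t  Bacteria",
    "83.33\t100\t100\tG\t1001\t    Alpha",
    "16.67\t20\t0\tD\t2759\t  Eukaryota",
    "16.67\t20\t20\tG\t9001\t    Yeastia"))
  pr <- readReport(p, "kraken2", sample = "s1")
  expect_equal(names(taxonProportions(pr)), "Alpha")
  expect_equal(unname(taxonProportions(pr)), 1)
})

test_that("empty and malformed reports give the promised signals", {
  onlyU <- writeLinesTmp("100.00\t50\t50\tU\t0\tunclassified")
  expect_error(readReport(onlyU, "kraken2", sample = "s1"),
               class = "emptyProfileError")
  bad <- writeLinesTmp(c(
    "0.00\t0\t0\tU\t0\tunclassified",
    "badly formed line"))
  expect_error(readReport(bad, "kraken2", sample = "s1"), "line 2")
  expect_error(readReport(tempfile(), "kraken2"), "not found")
})

test_that("a generic TSV with one taxon yields proportion 1", {
  p <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(sample = "s1", taxon = "Alpha", count = 42),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- readReport(p, "generic_tsv")$s1
  expect_equal(unname(taxonProportions(pr)), 1)
  expect_true(is.na(classifiedFraction(pr)))
})

test_that("every native writer round-trips through its reader", {
  tr <- generateTruth(seed = 6)
  phylumMap <- stats::setNames(genusInfo(tr)$phylum, genusInfo(tr)$genus)
  b <- biasModel("Any", classifiedFraction = 0.7, falsePositiveRate = 0,
                 depth = 2e4)
  obs <- observeWithClassifier(tr, b, seed = 1)
  want <- taxonProportions(observationProfiles(obs)$SW0)
  for (fmt in c("kraken2", "bracken", "kaiju", "amplicon", "generic_tsv")) {
    dir <- withr::local_tempdir()
    paths <- writeClassifierReports(obs, dir, format = fmt,
                                    phylumMap = phylumMap)
    pr <- switch(fmt,
                 amplicon = readReport(paths[1], fmt,
                                       taxonomyPath = paths[2])$SW0,
                 generic_tsv = readReport(paths[1], fmt)$SW0,
                 readReport(paths[grep("SW0", paths)], fmt,
                            sample = "SW0"))
    got <- taxonProportions(pr)
    expect_setequal(names(got), names(want))
    expect_equal(got[names(want)], want, tolerance = 1e-6,
                 info = fmt)
    if (fmt %in% c("kraken2", "kaiju"))
      expect_equal(classifiedFraction(pr), 0.7, tolerance = 1e-3)
  }
})

test_that("amplicon taxonomy strings are parsed with confidence stripping", {
  sh <- withr::local_tempfile(fileext = ".shared")
  tx <- withr::local_tempfile(fileext = ".taxonomy")
  write.table(data.frame(label = "0.03", Group = "s1", numOtus = 3,
                         Otu001 = 60, Otu002 = 30, Otu003 = 10),
              sh, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(
    OTU = c("Otu001", "Otu002", "Otu003"),
    Size = c(60, 30, 10),
    Taxonomy = c("Bacteria(100);Proteobacteria(99);Gamma(95);Fam(90);Alpha(88);",
                 "Bacteria(100);Bacteroidetes(99);Cl(95);Fam(90);Beta(85);",
                 "Eukaryota(100);Fungi(99);Cl(95);Fam(90);Yeastia(85);")),
    tx, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- readReport(sh, "amplicon", taxonomyPath = tx)$s1
  expect_equal(unname(taxonProportions(pr)[c("Alpha", "Beta")]),
               c(2 / 3, 1 / 3))
})

test_that("phylum-level aggregation pools genera and resolves classes", {
  pr <- TaxonomicProfile("s", "m", c(Pseudomonas = 0.5, Colwellia = 0.2,
                                     Ulvibacter = 0.3))
  map <- c(Pseudomonas = "Gammaproteobacteria",
           Colwellia = "Gammaproteobacteria", Ulvibacter = "Bacteroidetes")
  ph <- aggregateToPhylum(pr, map)
  expect_equal(unname(taxonProportions(ph)[c("Bacteroidetes",
                                             "Gammaproteobacteria")]),
               c(0.3, 0.7))
  expect_equal(profileLevel(ph), "phylum_with_proteo_classes")
})
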