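test_that("RPKG follows the normalization arithmetic", {
  expect_equal(rpkg(100, 1000, 10), 10)
  expect_equal(rpkg(0, 500, 3), 0)
  expect_error(rpkg(10, 0, 1), "length")
  expect_error(rpkg(10, 100, 0), "equivalents")
})

test_that("RPKG is linear in reads and inverse-linear in genome equivalents", {
  r <- rpkg(37, 840, 12)
  for (k in c(2, 10)) {
    expect_equal(rpkg(37 * k, 840, 12), r * k)
    expect_equal(rpkg(37, 840, 12 * k), r / k)
  }
})

test_that("group sums aggregate hand-computable toy tables", {
  defs <- data.frame(gene = c("gA", "gB", "gC"),
                     cluster = c("gA", "gB", "gC"),
                     group = c("aliphatic", "aliphatic", "PAH"),
                     length_bp = c(1000, 2000, 500))
  counts <- data.frame(sample = "s1", gene = c("gA", "gB", "gC"),
                       reads = c(100, 100, 50),
                       gene_length_bp = c(1000, 2000, 500),
                       genome_equivalents = 10)
  rp <- rpkgTable(counts, defs)
  expect_equal(unname(rp$groupSums["s1", c("PAH", "aliphatic")]),
               c(10, 15))
  expect_equal(unname(rp$totals[["s1"]]), 25)
  bad <- counts[, setdiff(names(counts), "gene_length_bp")]
  bad$gene[1] <- "unknown_gene"
  expect_error(rpkgTable(bad, defs), "missing gene length")
})

test_that("cluster presence uses a strict majority of components", {
  defs <- data.frame(gene = c("pmoA", "pmoB", "pmoC", "bsdC", "bsdD"),
                     cluster = c("pmoABC", "pmoABC", "pmoABC",
                                 "bsdCD", "bsdCD"),
                     group = "aliphatic", length_bp = 800)
  expect_true(clusterPresence(c("pmoA", "pmoB"), "pmoABC", defs))
  expect_true(clusterPresence(c("pmoA", "pmoB", "pmoC"), "pmoABC", defs))
  expect_false(clusterPresence("bsdC", "bsdCD", defs))  # exactly 50%
  expect_false(clusterPresence(character(0), "pmoABC", defs))
  expect_error(clusterPresence("x", "nope", defs), "unknown cluster")
})

test_that("quality filtering applies strict boundaries", {
  recs <- data.frame(mag = c("a", "b", "c", "d"),
                     completeness = c(50.0, 51.0, 80.0, 90.0),
                     contamination = c(5.0, 9.9, 10.0, 0.0))
  kept <- magQualityFilter(recs)
  expect_setequal(kept$mag, c("b", "d"))
  recs$completeness[1] <- 101
  expect_error(magQualityFilter(recs), "completeness")
})

test_that("quality filtering is monotone in completeness", {
  recs <- data.frame(mag = "m", completeness = 55, contamination = 5)
  expect_equal(nrow(magQualityFilter(recs)), 1)
  recs$completeness <- 95  # improving completeness never rejects
  expect_equal(nrow(magQualityFilter(recs)), 1)
})

test_that("dereplication is single linkage with an inclusive threshold", {
  ani <- data.frame(mag_a = c("A", "B", "A"), mag_b = c("B", "C", "C"),
                    ani = c(96, 96, 90))
  memb <- dereplicate(c("A", "B", "C"), ani)
  expect_equal(length(unique(memb)), 1)  # chain closure
  atCut <- data.frame(mag_a = "A", mag_b = "B", ani = 95.0)
  expect_equal(length(unique(dereplicate(c("A", "B"), atCut))), 1)
  below <- data.frame(mag_a = "A", mag_b = "B", ani = 94.99)
  expect_equal(length(unique(dereplicate(c("A", "B"), below))), 2)
})

test_that("dereplication output is a partition and inputs are validated", {
  set.seed(7)
  mags <- sprintf("m%02d", 1:12)
  pairs <- t(utils::combn(mags, 2))
  ani <- data.frame(mag_a = pairs[, 1], mag_b = pairs[, 2],
                    ani = stats::runif(nrow(pairs), 80, 99))
  memb <- dereplicate(mags, ani)
  expect_setequal(names(memb), mags)
  expect_false(anyNA(memb))
  expect_error(dereplicate(mags, ani, threshold = 101), "threshold")
  ani$ani[1] <- 120
  expect_error(dereplicate(mags, ani), "ANI outside")
  asym <- data.frame(mag_a = c("A", "B"), mag_b = c("B", "A"),
                     ani = c(96, 91))
  expect_error(dereplicate(c("A", "B"), asym), "asymmetric")
})

test_that("planted organism partitions are recovered exactly", {
  for (sd in 1:10) {
    m <- generateMags(nOrganisms = 4, magsPerOrganism = c(2, 3, 1, 4),
                      nLowQuality = 0, seed = sd)
    memb <- dereplicate(m$truth$mag, m$ani)
    planted <- m$truth$organism
    # same partition: every pair co-clustered iff co-planted
    pairs <- utils::combn(seq_along(planted), 2)
    expect_identical(unname(memb[m$truth$mag[pairs[1, ]]] ==
                              memb[m$truth$mag[pairs[2, ]]]),
                     planted[pairs[1, ]] == planted[pairs[2, ]])
  }
})

test_that("organism lanes mark full, partial and absent clusters", {
  defs <- data.frame(gene = c("pmoA", "pmoB", "pmoC", "almA", "nahC"),
                     cluster = c("pmoABC", "pmoABC", "pmoABC", "almA",
                                 "nahC"),
                     group = c(rep("aliphatic", 4), "PAH"),
                     length_bp = 900)
  memb <- c(m1 = 1L, m2 = 1L, m3 = 2L)
  hits <- data.frame(
    mag = c("m1", "m1", "m1", "m2", "m2", "m3"),
    gene = c("pmoA", "pmoB", "almA", "pmoA", "pmoB", "nahC"))
  prof <- magHdgProfile(hits, memb, defs)
  expect_equal(prof["organism1", "pmoABC"], "full")
  expect_equal(prof["organism1", "almA"], "partial")
  expect_equal(prof["organism1", "nahC"], "none")
  expect_equal(prof["organism2", "nahC"], "full")
  expect_equal(prof["organism2", "pmoABC"], "none")
})
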