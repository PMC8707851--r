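test_that("an exact doubling curve is fitted exactly", {
  fit <- windowOfLinearity(2^(1:30))
  expect_equal(fit$efficiency, 2, tolerance = 1e-6)
  expect_equal(fit$n0, 1, tolerance = 1e-6)
  expect_equal(fit$r2, 1)
  expect_identical(fit$flag, "")
})

test_that("flat curves raise the no-amplification signal", {
  flat <- rep(0.02, 40)
  expect_identical(windowOfLinearity(flat)$flag, "no-amplification")
  set.seed(1)
  noisy <- 0.02 + stats::rnorm(40, sd = 0.01)
  expect_identical(windowOfLinearity(noisy)$flag, "no-amplification")
  expect_error(windowOfLinearity(rep(1, 10)), "15 cycles")
})

test_that("efficiency and N0 are recovered from noisy logistic curves", {
  trueE <- 1.85; trueN0 <- 1e-7
  es <- n0s <- numeric(50)
  for (i in 1:50) {
    set.seed(i)
    f <- simulateCurve(curveParams(n0 = trueN0, efficiency = trueE,
                                   baseline = 0.02, fmax = 10,
                                   noiseSd = 0.1))
    fit <- windowOfLinearity(f)
    es[i] <- fit$efficiency; n0s[i] <- fit$n0
  }
  expect_lt(abs(stats::median(es) - trueE), 0.03)
  expect_lt(abs(stats::median(n0s) / trueN0 - 1), 0.15)
})

test_that("a sample identical to a standard recovers its copy number", {
  pl <- generateQpcrPlate(list(B16S = c(s = 1e3)), seed = 1, noiseSd = 0,
                          efficiencySd = 0)
  r <- quantResults(quantify(pl$plate, pl$meta))
  expect_equal(r$copies_per_reaction, 1000, tolerance = 0.01)
  # volumetric chain: elution 100 uL / template 1 uL / water 900 mL
  expect_equal(r$copies_per_ml, r$copies_per_reaction * 100 / 900)
})

test_that("standards quantified against each other self-recover within 10%", {
  stds <- standardSeries()
  pl <- generateQpcrPlate(list(B16S = stats::setNames(stds[2:7],
                                                      paste0("s", 2:7))),
                          seed = 1, noiseSd = 0, efficiencySd = 0,
                          replicates = 1)
  r <- quantResults(quantify(pl$plate, pl$meta))
  got <- r$copies_per_reaction[match(paste0("s", 2:7), r$sample)]
  expect_true(all(abs(got / stds[2:7] - 1) < 0.1))
})

test_that("quantified copies scale linearly with template on noiseless plates", {
  base <- 1e3
  pl <- generateQpcrPlate(list(B16S = c(x1 = base, x10 = 10 * base,
                                        x100 = 100 * base)),
                          seed = 1, noiseSd = 0, efficiencySd = 0)
  r <- quantResults(quantify(pl$plate, pl$meta))
  c1 <- r$copies_per_reaction[r$sample == "x1"]
  expect_equal(r$copies_per_reaction[r$sample == "x10"] / c1, 10,
               tolerance = 0.01)
  expect_equal(r$copies_per_reaction[r$sample == "x100"] / c1, 100,
               tolerance = 0.01)
})

test_that("synthetic-plate copy numbers are recovered within 20% (median)", {
  est <- numeric(50)
  for (i in 1:50) {
    pl <- generateQpcrPlate(list(B16S = c(s = 5e4)), seed = i)
    r <- quantResults(quantify(pl$plate, pl$meta))
    est[i] <- r$copies_per_reaction
  }
  expect_lt(abs(stats::median(est) / 5e4 - 1), 0.2)
})

test_that("relative abundances follow the 16S arithmetic", {
  q <- data.frame(sample = "s", target = c("B16S", "A16S", "Pseudomonas"),
                  copies_per_ml = c(1.0e6, 1.8e5, 1.0e6))
  rel <- relativeAbundance(q)
  expect_equal(rel$total_16s[1], 1.18e6)
  expect_equal(rel$archaea_pct[rel$target == "A16S"], 15.25, tolerance = 1e-3)
  expect_equal(rel$genus_pct[rel$target == "Pseudomonas"], 100)

  q0 <- data.frame(sample = "s", target = c("B16S", "A16S"),
                   copies_per_ml = c(1e6, 0))
  expect_equal(relativeAbundance(q0)$archaea_pct[2], 0)
  qMissing <- data.frame(sample = "s", target = "Pseudomonas",
                         copies_per_ml = 10)
  expect_error(relativeAbundance(qMissing), "B16S")
})

test_that("no-template controls are flagged when they amplify", {
  pl <- generateQpcrPlate(list(B16S = c(s = 1e3)), seed = 1, noiseSd = 0,
                          efficiencySd = 0)
  ntc <- pl$meta$well[pl$meta$role == "ntc"]
  contaminated <- simulateCurve(curveParams(n0 = 1e-6, efficiency = 1.85,
                                            baseline = 0.02, fmax = 10))
  pl$plate$fluorescence[pl$plate$well == ntc] <- contaminated
  r <- quantResults(quantify(pl$plate, pl$meta))
  expect_match(r$flags, "ntc-amplification")
})
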