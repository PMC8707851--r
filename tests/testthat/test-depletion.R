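test_that("percent depletion follows the concentration ratio", {
  expect_equal(percentDepletion(59, 100), 41)
  expect_equal(percentDepletion(5, 5), 0)
  expect_equal(percentDepletion(0, 7), 100)
  expect_error(percentDepletion(1, 0), "zero")
})

test_that("grouped depletion equals depletion of summed concentrations", {
  ct <- c(1, 2, 0.5, 3)
  c0 <- c(4, 4, 2, 6)
  grp <- c("2", "3", "3", ">=4")
  got <- percentDepletion(ct, c0, group = grp)
  expect_equal(unname(got[["3"]]), percentDepletion(2.5, 6))
  expect_equal(unname(got[["2"]]), 75)
})

test_that("biodegradation contribution is a flagged difference", {
  expect_equal(as.numeric(biodegradationContribution(41, 29)), 12)
  z <- biodegradationContribution(33, 33)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "no_detectable_biodegradation"))
  neg <- biodegradationContribution(30, 35)
  expect_equal(as.numeric(neg), -5)
  expect_true(attr(neg, "no_detectable_biodegradation"))
  expect_error(biodegradationContribution(120, 10), "\\[0, 100\\]")
  # antisymmetry of the roles
  expect_equal(as.numeric(biodegradationContribution(41, 29)),
               -as.numeric(biodegradationContribution(29, 41)))
})

test_that("biomarker ratios and their monotone-decrease flag behave", {
  expect_equal(biomarkerRatio(3, 3), 1)
  expect_error(biomarkerRatio(1, 0), "> 0")
  expect_true(isMonotoneDecreasing(c(2.0, 1.5, 1.0)))
  expect_false(isMonotoneDecreasing(c(2.0, 1.5, 1.6, 1.0)))
})

test_that("the ring-class map covers the 16 priority PAHs", {
  rc <- pahRingClasses()
  expect_length(rc, 16)
  expect_equal(unname(rc["naphthalene"]), "2")
  expect_equal(unname(rc["fluorene"]), "3")
  expect_equal(unname(rc["phenanthrene"]), "3")
  expect_equal(sum(rc == ">=4"), 10)
})

test_that("depletion metrics on the bundled table give the headline numbers", {
  dep <- depletionMetrics(readConcentrations())
  thc <- dep[dep$analyte == "THC", ]
  expect_equal(thc$depletion_pct[thc$treatment == "SWOs" &
                                   thc$time_months == 8], 29)
  expect_equal(thc$depletion_pct[thc$treatment == "SWOB" &
                                   thc$time_months == 8], 41)
  expect_equal(thc$biodegradation_pct[thc$treatment == "SWOB" &
                                        thc$time_months == 8], 12)
  # biomarker series decreases only under biostimulation
  conc <- readConcentrations()
  swob <- conc[conc$treatment == "SWOB", ]
  ratio <- vapply(c(0, 4, 8), function(tm)
    biomarkerRatio(
      swob$concentration[swob$analyte == "n-C17" &
                           swob$time_months == tm],
      swob$concentration[swob$analyte == "pristane" &
                           swob$time_months == tm]), 0)
  expect_true(isMonotoneDecreasing(ratio))
})
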