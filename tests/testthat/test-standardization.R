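test_that("national rates are pooled count / person-years per band", {
  expect_equal(nationalRates(c(30, 40), c(3000, 2000)), c(0.01, 0.02))
  expect_equal(nationalRates(c(0, 0), c(10, 10)), c(0, 0))
  expect_equal(nationalRates(100, 100), 1.0)
  expect_error(nationalRates(5, 0), "zero person-years")
  expect_error(nationalRates(c(1, 2), 3), "identical shape")
})

test_that("expected counts apply reference rates to area populations", {
  rates <- c(young = 0.01, old = 0.02)
  pop <- rbind(A = c(young = 1000, old = 500),
               B = c(young = 2000, old = 1500))
  e <- expectedCounts(pop, rates)
  expect_equal(unname(e["A"]), 20)
  expect_equal(unname(e["B"]), 50)

  pop0 <- rbind(A = c(young = 0, old = 0))
  e0 <- expectedCounts(pop0, rates)
  expect_equal(as.numeric(e0), 0)
  expect_identical(attr(e0, "zeroExpected"), "A")

  expect_error(expectedCounts(pop, c(young = 0.01, ancient = 0.02)),
               "labels")
})

test_that("self-standardization closure: sum(E) equals sum(O)", {
  set.seed(11)
  for (rep in 1:5) {
    nA <- sample(5:40, 1)
    pop <- matrix(runif(nA * 4, 100, 10000), nA,
                  dimnames = list(NULL, paste0("b", 1:4)))
    O <- matrix(rpois(nA * 4, pop * 0.002), nA)
    rates <- nationalRates(colSums(O), colSums(pop))
    E <- expectedCounts(pop, setNames(rates, paste0("b", 1:4)))
    expect_equal(sum(E), sum(O), tolerance = 1e-12)
  }
})

test_that("raw SMRs are O/E with undefined flag at E = 0", {
  r <- rawSMR(c(30, 0, 3), c(20, 5, 0))
  expect_equal(r$smr[1], 1.5)
  expect_equal(r$smr[2], 0)
  expect_true(is.na(r$smr[3]))
  expect_identical(r$undefined, c(FALSE, FALSE, TRUE))
  expect_error(rawSMR(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(rawSMR(1:3, 1:2), "length")
})

test_that("90%-range fold difference uses type-7 quantiles, half-up", {
  expect_equal(foldDifference(0.79, 1.31)$rounded, 1.7)
  expect_equal(foldDifference(0.85, 1.25)$rounded, 1.5)
  expect_equal(rangeRatio(rep(1.3, 10))$rounded, 1)

  set.seed(5)
  x <- exp(rnorm(500, 0, 0.2))
  rr <- rangeRatio(x)
  expect_equal(rr$raw, quantile(x, 0.95, names = FALSE) /
                 quantile(x, 0.05, names = FALSE))
  # scale invariance
  expect_equal(rangeRatio(3.7 * x)$raw, rr$raw, tolerance = 1e-12)
  # NA (undefined SMRs) are excluded, zero lower quantile is an error
  expect_equal(rangeRatio(c(x, NA, NA))$raw, rr$raw)
  expect_error(rangeRatio(c(rep(0, 10), rep(1, 5))), "not positive")
  expect_error(rangeRatio(1), "at least 2")
})

test_that("seven map categories are log-symmetric, left-closed", {
  cats <- categorizeSMR(c(0.95, 2.00, 0.49999, 0.5, 1.1, 1.4999, 0.67))
  expect_identical(cats$category_index, c(4L, 7L, 1L, 2L, 5L, 5L, 3L))
  expect_identical(as.character(cats$category_label[1]), "0.90-<1.10")
  expect_identical(as.character(cats$category_label[2]), ">=2.00")
  expect_error(categorizeSMR(-0.1), "nonnegative")
  expect_true(is.na(categorizeSMR(NA_real_)$category_index))

  # symmetry of the printed cutpoints on the log scale (to their 2-decimal
  # printed precision)
  expect_equal(log(0.50), -log(2.00), tolerance = 1e-12)
  expect_lt(abs(log(0.67) + log(1.50)), 0.01)
  expect_lt(abs(log(0.90) + log(1.10)), 0.011)
})

test_that("roundHalfUp rounds ties away from zero", {
  expect_equal(roundHalfUp(1.65, 1), 1.7)
  expect_equal(roundHalfUp(1.25, 1), 1.3)   # round() would give 1.2
  expect_equal(roundHalfUp(69.25, 1), 69.3)
  expect_equal(roundHalfUp(-1.25, 1), -1.3)
})
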