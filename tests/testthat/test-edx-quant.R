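test_that("relativeAtomicPercent normalises factor-weighted counts to 100", {
  eq <- relativeAtomicPercent(c(S = 500, Fe = 500, Ni = 500),
                              c(S = 1, Fe = 1, Ni = 1))
  expect_equal(unname(eq), rep(100 / 3, 3))
  expect_equal(sum(eq), 100)

  expect_equal(unname(relativeAtomicPercent(c(Ni = 123), c(Ni = 2))), 100)

  expect_error(relativeAtomicPercent(c(S = 0, Fe = 0), c(S = 1, Fe = 1)),
               "all-zero")
  expect_error(relativeAtomicPercent(c(S = 1, Fe = 1), c(S = 1)), "Fe")

  # any composition sums to 100 regardless of counts and factors
  set.seed(5)
  for (k in 1:20) {
    counts <- stats::setNames(sample(1:1e5, 3), c("S", "Fe", "Ni"))
    f <- stats::setNames(runif(3, 0.1, 10), c("S", "Fe", "Ni"))
    expect_equal(sum(relativeAtomicPercent(counts, f)), 100)
  }
})

test_that("fitSensitivityFactors round-trips published and random rows", {
  # published GS cross-section 1: counts and percents from the same row
  f <- fitSensitivityFactors(c(S = 1651, Fe = 5302, Ni = 40),
                             c(S = 13.0, Fe = 86.3, Ni = 0.7))
  expect_equal(unname(f[1]), 1)
  back <- relativeAtomicPercent(c(S = 1651, Fe = 5302, Ni = 40), f)
  expect_equal(unname(back), c(13.0, 86.3, 0.7), tolerance = 1e-6)

  # published RB cross-section 1
  fr <- fitSensitivityFactors(c(S = 1161, Fe = 180, Ni = 227),
                              c(S = 77.2, Fe = 9.8, Ni = 13.0))
  backr <- relativeAtomicPercent(c(S = 1161, Fe = 180, Ni = 227), fr)
  expect_equal(unname(backr), c(77.2, 9.8, 13.0), tolerance = 0.05)

  # unit case and scale invariance of the factors
  expect_equal(unname(fitSensitivityFactors(
    c(S = 10, Fe = 10), c(S = 50, Fe = 50))), c(1, 1))
  f10 <- fitSensitivityFactors(10 * c(S = 1651, Fe = 5302, Ni = 40),
                               c(S = 13.0, Fe = 86.3, Ni = 0.7))
  expect_equal(f, f10, tolerance = 1e-12)

  expect_error(fitSensitivityFactors(c(S = 0, Fe = 5), c(S = 10, Fe = 90)),
               "unsolvable")

  # round-trip identity on random strictly positive rows
  set.seed(9)
  for (k in 1:20) {
    counts <- stats::setNames(sample(10:1e5, 3), c("S", "Fe", "Ni"))
    pct <- stats::setNames(runif(3, 1, 10), c("S", "Fe", "Ni"))
    pct <- 100 * pct / sum(pct)
    fk <- fitSensitivityFactors(counts, pct)
    expect_equal(relativeAtomicPercent(counts, fk), pct, tolerance = 1e-9)
  }
})

test_that("elementalRatios reproduces published rows, symmetric pairs invert", {
  expect_equal(unname(round(
    elementalRatios(c(S = 31.4, Fe = 64.9, Ni = 3.8))["S:Fe"], 2)), 0.48)
  expect_equal(unname(round(
    elementalRatios(c(S = 13.0, Fe = 86.3, Ni = 0.7))["S:Fe"], 2)), 0.15)

  eq <- elementalRatios(c(S = 25, Fe = 25, Ni = 25))
  expect_equal(unname(eq), c(1, 1, 1))

  r <- elementalRatios(c(S = 31.4, Fe = 64.9), c("S:Fe", "Fe:S"))
  expect_equal(unname(r["S:Fe"] * r["Fe:S"]), 1)

  # zero denominator is undefined, not an error
  expect_true(is.na(elementalRatios(c(S = 10, Ni = 0), "S:Ni")))
})

test_that("summarizeCompositions reproduces the published outlier-excluded averages", {
  gs <- publishedEdxTable("GS")
  s <- summarizeCompositions(gs$percents, gs$ratios)
  expect_equal(s$excludedIds, "4")
  expect_equal(unname(round(s$elementMean["S"], 1)), 24.9)
  expect_equal(unname(round(s$elementSd["S"], 1)), 10.3)
  expect_equal(unname(round(s$elementMean["Fe"], 1)), 72.7)
  expect_equal(unname(round(s$ratioMean["S:Fe"], 2)), 0.36)
  expect_equal(unname(round(s$ratioMean["S:Ni"], 2)), 12.55)
  # published 5.53 came from unrounded per-row ratios; the printed rows
  # give 5.52 (documented last-digit recomputation effect)
  expect_equal(unname(round(s$ratioSd["S:Ni"], 2)), 5.52)

  rb <- publishedEdxTable("RB")
  sr <- summarizeCompositions(rb$percents, rb$ratios)
  expect_equal(unname(round(sr$elementMean["S"], 1)), 78.6)
  expect_equal(unname(round(sr$elementSd["S"], 1)), 3.3)
  expect_equal(unname(round(sr$elementMean["Ni"], 1)), 10.4)
  expect_equal(unname(round(sr$ratioMean["S:Ni"], 2)), 8.26)
  expect_equal(unname(round(sr$ratioMean["Fe:Ni"], 2)), 1.14)

  # ratio-of-means mode differs from mean-of-ratios by construction
  sm <- summarizeCompositions(gs$percents, gs$ratios,
                              ratioMode = "from_percents")
  expect_equal(unname(sm$ratioMean["S:Fe"]),
               sm$elementMean[["S"]] / sm$elementMean[["Fe"]])

  expect_error(summarizeCompositions(
    data.frame(section_id = 1, S = 10, Fe = 90, outlier = TRUE)),
    "outliers")
})

test_that("Poisson-simulated regions recover the planted composition", {
  truth <- c(S = 24.9, Fe = 72.7, Ni = 2.4)
  regions <- simEDXCounts(50, truth, totalCounts = 1e4, seed = 21)
  f <- attr(regions, "factors")
  pct <- t(apply(regions[, names(truth)], 1, relativeAtomicPercent, f))
  recovered <- colMeans(pct)
  expect_true(all(abs(recovered - truth) < 1))
})
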