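test_that("fitIV recovers exact lines and matches closed-form OLS on noise", {
  # exact line through the origin
  fit <- fitIV(c(-1, 0, 1), c(-2e-9, 0, 2e-9))
  expect_equal(fit@slope, 2e-9)
  expect_equal(fit@intercept, 0)
  expect_equal(fit@rSquared, 1)

  # flat line: zero slope, defined r^2
  flat <- fitIV(c(0, 1), c(5e-12, 5e-12))
  expect_equal(flat@slope, 0)
  expect_equal(flat@intercept, 5e-12)
  expect_equal(flat@rSquared, 1)

  # noisy 11-point sweep against the normal-equations oracle
  set.seed(11)
  v <- seq(-1, 1, length.out = 11)
  i <- 3.2e-9 * v + 1e-11 + rnorm(11, 0, 2e-10)
  fit <- fitIV(v, i)
  oracle <- olsOracle(v, i)
  expect_equal(fit@slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit@intercept, oracle$intercept, tolerance = 1e-12)

  expect_error(fitIV(c(1, 1, 1), c(1, 2, 3)), "degenerate")
})

test_that("LOD censoring is strict below the limit, boundary detectable", {
  cfg <- AnalysisConfig(lodConductance = 1e-12)
  mk <- function(s) new("OhmicFit", slope = s, intercept = 0, rSquared = 1)
  expect_true(isBelowLOD(mk(0.5e-12), cfg))
  expect_false(isBelowLOD(mk(1e-12), cfg))   # boundary counts as detectable
  expect_false(isBelowLOD(mk(2e-9), cfg))
  expect_true(isBelowLOD(mk(-0.5e-12), cfg)) # magnitude, not sign
})

test_that("PCF count and area follow the strain geometry model", {
  hou <- StrainGeometry("Hou", 850)
  expect_identical(pcfCountFromDiameter(1.0, hou), 16L) # 5*pi = 15.708
  expect_identical(pcfCountFromDiameter(0, hou), 0L)
  expect_identical(pcfCountFromDiameter(2.0, hou), 31L) # 31.416
  expect_error(pcfCountFromDiameter(-1, hou), "non-negative")

  expect_equal(totalPCFArea(34, geometryPreset("GS")), 28900)
  expect_equal(totalPCFArea(15, geometryPreset("RB")), 16500)
  expect_equal(totalPCFArea(1, geometryPreset("GS")), 850)
  expect_error(totalPCFArea(0, geometryPreset("GS")), ">= 1")

  # fixed count wins over the diameter formula
  expect_identical(resolvePcfCount(geometryPreset("GS"), diameter = 10), 34L)
  expect_identical(resolvePcfCount(hou, diameter = 1.0), 16L)
  expect_error(resolvePcfCount(hou), "diameter")
})

test_that("conductivity applies sigma = I*l/(V*A) with unit discipline", {
  v <- seq(-1, 1, 0.1)
  sw <- IVSweep("f1", "GS", v, 1e-8 * v, gapLength = 300)
  fit <- fitIV(sw)
  res <- conductivity(fit, sw, area = 28900)
  # slope 10 nA/V -> I = 1 nA at 0.1 V; (1e-9 * 300e-6)/(0.1 * 2.89e-14)
  # = 103.8 S/m = 1.038 S/cm
  expect_equal(res$currentAtEval, 1e-9)
  expect_equal(res$sigmaSPerCm, 1.038062, tolerance = 1e-6)
  expect_false(res$belowLod)

  # linear in gap, inverse in area
  sw2 <- IVSweep("f2", "GS", v, 1e-8 * v, gapLength = 600)
  expect_equal(conductivity(fit, sw2, 28900)$sigmaSPerCm,
               2 * res$sigmaSPerCm)
  expect_equal(conductivity(fit, sw, 2 * 28900)$sigmaSPerCm,
               res$sigmaSPerCm / 2)

  # zero slope gives zero evaluated current and is censored under any
  # positive detection limit, so sigma is reported as absent
  zfit <- new("OhmicFit", slope = 0, intercept = 0, rSquared = 1)
  zres <- conductivity(zfit, sw, 28900)
  expect_equal(zres$currentAtEval, 0)
  expect_true(zres$belowLod)
  expect_true(is.na(zres$sigmaSPerCm))

  expect_error(conductivity(fit, sw, area = 0), "area")
})

test_that("cohort summaries exclude censored results and keep n accounting", {
  res <- data.frame(sigmaSPerCm = c(1, 2, 3), belowLod = FALSE)
  s <- summarizeCohort(res)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$median, 2)

  res2 <- data.frame(sigmaSPerCm = c(4, 4, NA),
                     belowLod = c(FALSE, FALSE, TRUE))
  s2 <- summarizeCohort(res2)
  expect_equal(s2$mean, 4)
  expect_equal(s2$nBelowLod, 1)
  expect_equal(s2$nTotal, 3)

  # all-censored cohort: counts only
  s3 <- summarizeCohort(data.frame(sigmaSPerCm = NA_real_, belowLod = TRUE))
  expect_equal(s3$nBelowLod, 1)
  expect_true(is.na(s3$mean))

  # Tukey conventions on a cohort with one far outlier
  x <- c(1, 2, 3, 4, 5, 50)
  s4 <- summarizeCohort(data.frame(sigmaSPerCm = x, belowLod = FALSE))
  expect_true(s4$q1 <= s4$median && s4$median <= s4$q3)
  expect_true(s4$whiskerLow >= min(x) && s4$whiskerHigh <= max(x))
  iqr <- s4$q3 - s4$q1
  expect_true(s4$whiskerHigh <= s4$q3 + 1.5 * iqr)
  expect_equal(s4$outliers, 50)
  expect_equal(s4$nTotal, length(x))
})

test_that("synthetic cohorts recover the true conductivity across the range", {
  # parameter recovery at several true sigmas, n = 100, 5% noise
  for (sigma in c(0.1, 4, 25)) {
    sweeps <- simIVSweeps(100, trueSigma = sigma, noiseFraction = 0.05,
                          seed = 300 + round(sigma * 10))
    res <- do.call(rbind, lapply(sweeps, function(s)
      analyzeSweep(s, geometryPreset("GS"))))
    s <- summarizeCohort(res)
    expect_lt(abs(s$mean - sigma) / sigma, 0.05)
  }
})
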