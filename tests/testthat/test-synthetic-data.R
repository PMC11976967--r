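test_that("generators are pure functions of their seed", {
  s1 <- simIVSweeps(5, seed = 3)
  s2 <- simIVSweeps(5, seed = 3)
  expect_identical(lapply(s1, function(x) x@currents),
                   lapply(s2, function(x) x@currents))
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))

  expect_identical(simEDXCounts(5, seed = 3), simEDXCounts(5, seed = 3))
  expect_identical(simIsotopeCounts(1e4, seed = 3),
                   simIsotopeCounts(1e4, seed = 3))
  expect_identical(simVesicles(20, seed = 3), simVesicles(20, seed = 3))
  expect_identical(simProteomePair(2, 2, seed = 3,
                                   hemeCounts = c(1L, 0L),
                                   lengths = c(100L, 100L)),
                   simProteomePair(2, 2, seed = 3,
                                   hemeCounts = c(1L, 0L),
                                   lengths = c(100L, 100L)))

  # the global RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simIVSweeps(3, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("noise-free sweeps invert exactly; censored sweeps sit below LOD", {
  sweeps <- simIVSweeps(10, trueSigma = 2.5, noiseFraction = 0,
                        lodFraction = 0, seed = 8)
  res <- do.call(rbind, lapply(sweeps, function(s)
    analyzeSweep(s, geometryPreset("GS"))))
  expect_equal(res$sigmaSPerCm, rep(2.5, 10), tolerance = 1e-9)

  # gaps drawn inside the instrument's working range
  gaps <- vapply(sweeps, function(s) s@gapLength, numeric(1))
  expect_true(all(gaps >= 100 & gaps <= 800))

  cens <- simIVSweeps(20, trueSigma = 4, noiseFraction = 0,
                      lodFraction = 0.25, seed = 8)
  resc <- do.call(rbind, lapply(cens, function(s)
    analyzeSweep(s, geometryPreset("GS"))))
  expect_equal(sum(resc$belowLod), 5)
  expect_identical(resc$belowLod, attr(cens, "truth")$censored)
  # censored sweeps are generated at a tenth of the LOD, not at zero
  expect_true(all(resc$conductance[resc$belowLod] > 0))

  expect_error(simIVSweeps(5, lodFraction = 1.5), "lodFraction")
})

test_that("expected-mode EDX counts quantify back to the planted truth", {
  truth <- c(S = 30, Fe = 65, Ni = 5)
  f <- c(S = 1, Fe = 2, Ni = 0.5)
  regions <- simEDXCounts(3, truth, totalCounts = 1e4, factors = f,
                          mode = "expected", seed = 1)
  for (i in 1:3) {
    counts <- unlist(regions[i, names(truth)])
    expect_equal(relativeAtomicPercent(counts, f), truth,
                 tolerance = 1e-9)
  }
  expect_error(simEDXCounts(3, c(S = 50, Fe = 40)), "sum to 100")
})

test_that("expected-mode isotope counts equal abundance arithmetic", {
  x <- simIsotopeCounts(97940, mode = "expected")
  expect_equal(unname(x), c(68080, 26220, 3640))
  fr <- relativeIsotopeCounts(simIsotopeCounts(1e4, seed = 2))
  expect_equal(sum(fr), 1)
  expect_error(simIsotopeCounts(0), "totalCounts")
})

test_that("planted proteomes honour motif counts, classes and masking", {
  pp <- simProteomePair(seed = 42)
  annA <- annotateProteome(pp$proteomeA)
  annB <- annotateProteome(pp$proteomeB)
  hom <- pp$truth
  # planted heme counts are exact on both sides (mutation never destroys
  # a planted motif, and planted backgrounds are cysteine-free)
  expect_equal(annA$n_hemes[match(hom$id_a, annA$protein_id)],
               hom$heme_count)
  expect_equal(annB$n_hemes[match(hom$id_b, annB$protein_id)],
               hom$heme_count)
  expect_equal(annA$class[match(hom$id_a, annA$protein_id)], hom$class)

  # pentaheme length-180 plant classifies sPHC at the default threshold
  expect_true("pentaheme_sPHC" %in% hom$class)
  expect_true("pentaheme_lPHC" %in% hom$class)

  # zero mutation rate gives identical partners
  pp0 <- simProteomePair(2, 2, mutationRate = 0, hemeCounts = c(2L, 0L),
                         lengths = c(120L, 100L), seed = 5)
  expect_equal(unname(pp0$proteomeA[pp0$truth$id_a]),
               unname(pp0$proteomeB[pp0$truth$id_b]))

  expect_error(simProteomePair(mutationRate = 0.5), "mutationRate")
  expect_error(simProteomePair(1, 1, hemeCounts = 5L, lengths = 20L),
               "cannot hold")
})
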