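test_that("scanHemeMotifs finds CXXCH windows under both overlap policies", {
  expect_equal(scanHemeMotifs("CAACH")$motifStarts, 0L)
  expect_equal(scanHemeMotifs("AAAAA")$hemeCount, 0L)
  expect_equal(scanHemeMotifs("CAACHACH")$hemeCount, 1L)
  expect_equal(scanHemeMotifs("CAACHACH", overlap = "all")$motifStarts,
               c(0L, 3L))

  # X never matches the C or H positions, may sit in a wildcard position
  expect_equal(scanHemeMotifs("XAACH")$hemeCount, 0L)
  expect_equal(scanHemeMotifs("CAACX")$hemeCount, 0L)
  expect_equal(scanHemeMotifs("CXXCH")$hemeCount, 1L)

  # configurable internal gap: CX3CH
  expect_equal(scanHemeMotifs("CAAACH", nInternal = 3)$motifStarts, 0L)
  expect_equal(scanHemeMotifs("CAAACH")$hemeCount, 0L)

  expect_error(scanHemeMotifs(""), "empty")
  expect_error(scanHemeMotifs("CAACH1"), "non-amino-acid")

  # all-matches mode equals brute-force window enumeration
  set.seed(41)
  for (k in 1:50) {
    seq <- randomPeptide(sample(5:120, 1), c(AA20, "X"))
    expect_identical(
      scanHemeMotifs(seq, overlap = "all")$motifStarts,
      motifOracle(seq),
      info = seq)
  }
})

test_that("cytochrome classes follow heme count and the sPHC length split", {
  expect_equal(classifyCytochrome(0, 100), "none")
  expect_equal(classifyCytochrome(1, 100), "monoheme")
  expect_equal(classifyCytochrome(4, 400), "multiheme") # tetraheme case
  expect_equal(classifyCytochrome(5, 180), "pentaheme_sPHC")
  expect_equal(classifyCytochrome(5, 600), "pentaheme_lPHC")
  expect_equal(classifyCytochrome(5, 250), "pentaheme_sPHC") # boundary
  expect_equal(classifyCytochrome(10, 900), "multiheme")
  expect_error(classifyCytochrome(5, 100, sphcMaxLength = -1), "negative")
})

test_that("localAlign equals the quadratic DP oracle and is symmetric", {
  scheme <- ScoringScheme()
  mat <- pcfQuant:::.schemeMatrix(scheme)

  # identical peptide scores the sum of its diagonal substitution values
  pep <- "HEAGAWGHEE"
  diag <- sum(vapply(strsplit(pep, "")[[1]], function(a) mat[a, a],
                     numeric(1)))
  expect_equal(localAlign(pep, pep), diag)

  set.seed(13)
  for (k in 1:25) {
    a <- randomPeptide(30)
    b <- randomPeptide(30)
    s <- localAlign(a, b, scheme)
    expect_gte(s, 0)
    expect_equal(s, localAlign(b, a, scheme)) # symmetry
    expect_equal(s, swOracle(a, b, mat, scheme@gapOpen, scheme@gapExtend))
  }

  # lenient vs strict X handling
  expect_equal(localAlign("AXA", "AXA"),
               2 * mat["A", "A"]) # X contributes 0
  expect_error(localAlign("AXA", "AAA", ScoringScheme(lenient = FALSE)),
               "strict")
})

test_that("reciprocal best hits recover planted homologs and swap symmetrically", {
  # identical proteomes map to themselves
  prots <- c(p1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
             p2 = "GDVEKGKKIFIMKCSQCHTVEKGGKHKTGPNLH",
             p3 = "MDALKMTMMVLAIGGGSLAHAADVVSAPAASGT")
  rbh <- reciprocalBestHits(prots, prots, minScore = 10)
  expect_true(all(rbh$reciprocal))
  expect_equal(rbh$id_a, rbh$id_b)

  expect_equal(nrow(reciprocalBestHits(character(), prots)), 0L)
  expect_error(reciprocalBestHits(c(a = "MK", a = "MR"), prots),
               "duplicate")

  # planted pairs at 10% mutation: exact recovery, no decoy pairs
  pp <- simProteomePair(nHomologs = 4, nDecoys = 5, mutationRate = 0.10,
                        hemeCounts = c(5L, 2L, 1L, 0L),
                        lengths = c(180L, 300L, 250L, 200L), seed = 7)
  rbh <- reciprocalBestHits(pp$proteomeA, pp$proteomeB)
  rec <- rbh[rbh$reciprocal, ]
  expect_setequal(paste(rec$id_a, rec$id_b),
                  paste(pp$truth$id_a, pp$truth$id_b))

  # swapping the proteomes exchanges the roles, same pairs
  back <- reciprocalBestHits(pp$proteomeB, pp$proteomeA)
  brec <- back[back$reciprocal, ]
  expect_setequal(paste(brec$id_b, brec$id_a),
                  paste(rec$id_a, rec$id_b))
})

test_that("the census keeps two-sided cytochromes and reports discordance", {
  pp <- simProteomePair(nHomologs = 4, nDecoys = 3, mutationRate = 0.05,
                        hemeCounts = c(5L, 3L, 1L, 0L),
                        lengths = c(180L, 300L, 250L, 200L), seed = 19)
  res <- conservedCytochromeCensus(pp$proteomeA, pp$proteomeB)
  truth <- pp$truth[pp$truth$heme_count >= 1, ]
  expect_setequal(paste(res$census$id_a, res$census$id_b),
                  paste(truth$id_a, truth$id_b))
  expect_equal(res$counts$nConserved, 3)
  expect_equal(res$counts$nPentaheme, 1)
  expect_equal(res$census$class_a, res$census$class_b)

  # no motifs anywhere: empty census
  plain <- c(q1 = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  empty <- conservedCytochromeCensus(plain, plain, minScore = 10)
  expect_equal(nrow(empty$census), 0L)

  # a motif on one side only is discordant, not census
  a <- c(x = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPWAA")
  b <- c(y = "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQCAACH")
  one <- conservedCytochromeCensus(a, b, minScore = 10)
  expect_equal(nrow(one$census), 0L)
  expect_equal(nrow(one$discordant), 1L)
})
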