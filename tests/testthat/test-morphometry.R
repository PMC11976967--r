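test_that("pcfArea computes circular and rectangular cross-sections", {
  expect_equal(pcfArea(PCFShape("GS", "circular", diameter = 30.89)),
               749.4, tolerance = 1e-3)
  expect_equal(pcfArea(PCFShape("RB", "rectangular",
                                height = 25.95, width = 43.01)),
               1116.1, tolerance = 1e-4)
  expect_equal(pcfArea(PCFShape("x", "circular", diameter = 2)), pi)
  expect_error(PCFShape("x", "circular", diameter = -1), "positive")
  expect_error(PCFShape("x", "rectangular", height = 5), "width")

  # monotone in every dimension
  expect_gt(pcfArea(PCFShape("x", "circular", diameter = 31)),
            pcfArea(PCFShape("x", "circular", diameter = 30)))
  expect_gt(pcfArea(PCFShape("x", "rectangular", height = 26, width = 43)),
            pcfArea(PCFShape("x", "rectangular", height = 25, width = 43)))
})

test_that("single-PCF comparison: RB measured area is ~50% larger than GS", {
  cmp <- compareSinglePCFArea(shapePreset("GS"), shapePreset("RB"))
  expect_equal(cmp$rounded, 50)
  expect_equal(cmp$percent, 48.93, tolerance = 1e-3)

  same <- compareSinglePCFArea(shapePreset("GS"), shapePreset("GS"))
  expect_equal(same$percent, 0)

  dbl <- compareSinglePCFArea(
    PCFShape("a", "rectangular", height = 10, width = 10),
    PCFShape("b", "rectangular", height = 10, width = 20))
  expect_equal(dbl$percent, 100)
})

test_that("total-PCF comparison distinguishes model and measured presets", {
  model <- compareTotalPCFArea(34, pcfAreaPreset("GS", "model"),
                               15, pcfAreaPreset("RB", "model"))
  expect_equal(model$totalA, 28900)
  expect_equal(model$totalB, 16500)
  expect_equal(model$rounded, -40)
  expect_equal(model$percent, -42.91, tolerance = 1e-3)

  meas <- compareTotalPCFArea(34, pcfAreaPreset("GS", "measured"),
                              15, pcfAreaPreset("RB", "measured"))
  expect_equal(meas$percent, -34.3, tolerance = 1e-2)

  expect_equal(compareTotalPCFArea(10, 100, 10, 100)$percent, 0)
  expect_error(compareTotalPCFArea(0, 100, 10, 100), ">= 1")
})

test_that("vesicle summaries report IMAV fraction and per-class statistics", {
  v <- data.frame(diameter = c(60, 70, 65),
                  attachment = c("IMAV", "IMAV", "CV"))
  s <- summarizeVesicles(v)
  expect_equal(s$imavFraction, 2 / 3)
  expect_equal(s$byClass$mean[s$byClass$class == "IMAV"], 65)
  expect_equal(s$nIMAV + s$nCV, s$nTotal)

  # RB-like: every vesicle attached to the inner membrane
  allimav <- summarizeVesicles(data.frame(diameter = c(55, 60),
                                          attachment = "IMAV"))
  expect_equal(allimav$imavFraction, 1)

  expect_error(summarizeVesicles(data.frame(diameter = numeric(),
                                            attachment = character())),
               "empty")
  expect_error(summarizeVesicles(data.frame(diameter = 1,
                                            attachment = "other")),
               "unknown attachment")
})

test_that("synthetic vesicles recover the planted fraction and diameter", {
  v <- simVesicles(500, imavFraction = 0.9, meanDiameter = 65.5,
                   sdDiameter = 4.6, seed = 17)
  s <- summarizeVesicles(v)
  expect_lt(abs(s$imavFraction - 0.9), 0.03)
  imavMean <- s$byClass$mean[s$byClass$class == "IMAV"]
  expect_lt(abs(imavMean - 65.5), 0.5)
})
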