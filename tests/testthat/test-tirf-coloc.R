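test_that("ROI gating follows the either-channel OR rule", {
  sc <- twoChannelScene(matrix(c(0, 10, 0, 10), 2), matrix(c(0, 0, 10, 0), 2))
  mask <- selectRoiPixels(sc, thresholdSpec(value = 5), thresholdSpec(value = 5))
  expect_equal(as.vector(mask), c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(sum(mask), 3L)

  zero <- twoChannelScene(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(sum(selectRoiPixels(zero, thresholdSpec(value = 1),
                                   thresholdSpec(value = 1))), 0L)

  full <- twoChannelScene(matrix(10, 4, 4), matrix(0, 4, 4))
  expect_true(all(selectRoiPixels(full, thresholdSpec(value = 5),
                                  thresholdSpec(value = 5))))
})

test_that("contact area converts pixel counts at the camera pixel size", {
  expect_equal(contactArea(matrix(FALSE, 8, 8)), 0)
  expect_equal(contactArea(matrix(TRUE, 1, 1)), 0.0256)
  expect_equal(contactArea(matrix(TRUE, 40, 25)), 25.6)  # 1000 pixels
  expect_equal(contactArea(matrix(TRUE, 1, 1), pixelSizeLateral = 100), 0.01)
})

test_that("the correlation formula reproduces hand-worked values", {
  sc <- twoChannelScene(matrix(1:4, 2), matrix(c(2, 1, 4, 3), 2))
  expect_equal(pearsonCC(sc, matrix(TRUE, 2, 2)), 0.6)

  x <- matrix(c(1, 5, 2, 9, 4, 7), 2)
  expect_equal(pearsonCC(twoChannelScene(x, x), matrix(TRUE, 2, 3)), 1)
  expect_equal(pearsonCC(twoChannelScene(x, 3 * x + 2), matrix(TRUE, 2, 3)), 1)
  expect_equal(pearsonCC(twoChannelScene(x, -2 * x + 30),
                         matrix(TRUE, 2, 3)), -1)
})

test_that("degenerate correlation inputs are flagged, not zeroed", {
  x <- matrix(c(1, 5, 2, 9), 2)
  sc <- twoChannelScene(x, matrix(3, 2, 2))
  expect_true(is.na(pearsonCC(sc, matrix(TRUE, 2, 2))))  # zero variance
  mask1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_error(pearsonCC(sc, mask1), class = "SynapseColoc_insufficientData")
})

test_that("correlation is invariant under positive affine rescaling", {
  withr::local_seed(99)
  for (i in 1:20) {
    x <- matrix(runif(64, 0, 100), 8)
    y <- matrix(runif(64, 0, 100), 8)
    mask <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, c(0.7, 0.3)), 8)
    if (sum(mask) < 3) next
    r0 <- pearsonCC(twoChannelScene(x, y), mask)
    r1 <- pearsonCC(twoChannelScene(2.5 * x + 7, 0.3 * y + 11), mask)
    expect_lt(abs(r0 - r1), 1e-10)
  }
})

test_that("gating out the dark border changes the correlation as intended", {
  # perfectly correlated signal on a central disc, independent dim noise on
  # the border: the border adds uncorrelated variance, so restricting to
  # gated pixels must increase the measured correlation
  withr::local_seed(7)
  n <- 64
  d <- SynapseColoc:::.discRegionMap2D(c(n, n), 0.16, 3)
  g <- matrix(rpois(n * n, 5), n)
  r <- matrix(rpois(n * n, 5), n)
  sig <- matrix(pmax(100 + rnorm(n * n, 0, 30), 0), n)
  g[d] <- sig[d]
  r[d] <- sig[d]
  sc <- twoChannelScene(g, r)
  ungated <- pearsonCC(sc, matrix(TRUE, n, n))
  gated <- pearsonCC(sc, selectRoiPixels(sc, thresholdSpec(value = 20),
                                         thresholdSpec(value = 20)))
  expect_equal(gated, 1)
  expect_gt(gated, ungated)
})

test_that("a noise-free perfect-copy cell recovers its contact disc", {
  tr <- sceneTruth("tirf2d", colocFraction = 1, enrichmentGreen = 3,
                   enrichmentRed = 3, shotNoise = FALSE, readNoiseSd = 0,
                   seed = 5)
  m <- analyzeTirfCell(generateTirfScene(tr))
  expect_equal(m@pcc, 1)
  trueArea <- pi * tr@cellRadius^2
  ringTol <- 4 * pi * tr@cellRadius * tr@pixelSizeLateral / 1000
  expect_lt(abs(m@contactArea - trueArea), ringTol)
})

test_that("a zero-signal cell yields an empty ROI and an undefined PCC", {
  tr <- smallTirfTruth(photonsPerReceptor = 0, background = 5,
                       readNoiseSd = 0, shotNoise = FALSE, seed = 1)
  m <- analyzeTirfCell(generateTirfScene(tr))
  expect_equal(m@contactArea, 0)
  expect_true(is.na(m@pcc))
  expect_true("undefined_pcc" %in% m@flags)
})

test_that("probe conditions order the TIRF correlation medians correctly", {
  scenes <- generateCohort(synapseConditions("tirf2d"), 6, seed = 11)
  df <- measurementsToDataFrame(lapply(scenes, analyzeTirfCell))
  med <- summarizeGroups(df, "pcc")
  med <- setNames(med$median, med$condition)
  expect_gt(med[["CAR_CAR"]], 0.8)
  expect_lt(abs(med[["CAR_TCR"]]), 0.3)
  expect_lt(abs(med[["CAR_TFR"]]), 0.3)
  expect_gt(med[["CAR_CAR"]] - max(med[["CAR_TCR"]], med[["CAR_TFR"]]), 0.5)
  expect_lt(abs(med[["CAR_TCR"]] - med[["CAR_TFR"]]), 0.2)
})

test_that("contact size is coating-independent while enrichment is not", {
  # CAR target (HER2 surface): green receptor engaged and enriched;
  # TCR target (OKT3 surface): red receptor engaged, green unenriched.
  her2 <- sceneTruth("tirf2d", enrichmentGreen = 3, enrichmentRed = 0.5,
                     condition = "HER2")
  okt3 <- sceneTruth("tirf2d", enrichmentGreen = 1, enrichmentRed = 3,
                     condition = "OKT3")
  scenes <- generateCohort(list(her2, okt3), 6, seed = 3)
  df <- measurementsToDataFrame(lapply(scenes, analyzeTirfCell))
  areas <- summarizeGroups(df, "contact_area_um2")
  areas <- setNames(areas$mean, areas$condition)
  expect_lt(abs(areas[["HER2"]] - areas[["OKT3"]]) / areas[["OKT3"]], 0.3)
  greenMeans <- vapply(scenes, function(s)
    mean(greenChannel(s)[selectRoiPixels(s)]), 0)
  isHer2 <- df$condition == "HER2"
  expect_gt(mean(greenMeans[isHer2]), 2 * mean(greenMeans[!isHer2]))
})
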