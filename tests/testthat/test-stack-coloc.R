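test_that("the box mean filter preserves constants, impulses and ramps", {
  const <- array(4.2, c(9, 9, 9))
  expect_identical(meanFilter3D(const), const)

  imp <- array(0, c(15, 15, 15)); imp[8, 8, 8] <- 1
  f <- meanFilter3D(imp)
  box <- array(FALSE, c(15, 15, 15)); box[5:11, 5:11, 5:11] <- TRUE
  expect_equal(unique(f[box]), 1 / 343)
  expect_true(all(f[!box] == 0))

  ramp <- array(rep(1:20, each = 1), c(20, 9, 9))
  fr <- meanFilter3D(ramp)
  expect_equal(fr[4:17, 5, 5], ramp[4:17, 5, 5])  # interior unchanged
})

test_that("filter radius bounds are enforced", {
  a <- array(0, c(5, 5, 5))
  expect_error(meanFilter3D(a, 0), class = "SynapseColoc_invalidParameter")
  expect_error(meanFilter3D(a, c(3, 3, 6)),
               class = "SynapseColoc_invalidParameter")
  expect_error(meanFilter3D(matrix(0, 3, 3)),
               class = "SynapseColoc_invalidParameter")
})

test_that("segmentation keeps only the largest connected component", {
  a <- array(0, c(20, 20, 20))
  a[2:11, 2:11, 2:11] <- 10      # 1000 voxels
  a[15:19, 15:19, 15:18] <- 10   # 100 voxels, detached
  mask <- segmentRoi3D(a, thresholdSpec(value = 5), "synaptic")
  expect_equal(sum(mask), 1000L)
  expect_true(all(which(mask) == which(a > 5 &
    slice.index(a, 1) <= 11)))

  expect_error(segmentRoi3D(array(1, c(6, 6, 6)), thresholdSpec("otsu"),
                            "synaptic"),
               class = "SynapseColoc_emptySegmentation")
})

test_that("the synaptic segmentation recovers the true contact region", {
  tr <- sceneTruth("stack3d", seed = 11)
  sc <- generateStackScene(tr)
  gf <- meanFilter3D(greenChannel(sc))
  zStar <- which.max(apply(greenChannel(sc), 3, sum))
  syn <- segmentRoi3D(gf, anchor = "synaptic",
                      zRange = c(zStar - 1, zStar + 2))
  truthRegion <- SynapseColoc:::.dilateBox(truthMasks(tr)$synaptic, c(3, 3, 3))
  expect_gt(diceCoef(syn, truthRegion), 0.5)
})

test_that("ROI merging keeps regions disjoint with an exact union", {
  d <- c(6, 6, 6)
  g <- array(FALSE, d); g[1:3, , ] <- TRUE
  r <- array(FALSE, d); r[5:6, , ] <- TRUE
  rois <- buildRoiSet(g, r)
  expect_identical(rois@extrasynaptic, r)  # disjoint inputs unchanged
  expect_true(validObject(rois))

  rSub <- array(FALSE, d); rSub[2, , ] <- TRUE  # red inside green
  rois2 <- buildRoiSet(g, rSub)
  expect_equal(sum(rois2@extrasynaptic), 0L)
  expect_identical(rois2@wholeCell, g)

  withr::local_seed(3)
  gR <- array(runif(prod(d)) > 0.5, d)
  rR <- array(runif(prod(d)) > 0.5, d)
  rois3 <- buildRoiSet(gR, rR)
  expect_equal(sum(rois3@wholeCell), sum(gR) + sum(rR & !gR))

  expect_error(buildRoiSet(array(FALSE, d), array(FALSE, d)),
               class = "SynapseColoc_invalidParameter")
})

test_that("relative intensities follow closed-form means and their identity", {
  d <- c(8, 8, 4)
  syn <- array(FALSE, d); syn[1:4, , ] <- TRUE
  ext <- array(FALSE, d); ext[5:8, , ] <- TRUE
  rois <- buildRoiSet(syn, ext)

  uni <- twoChannelScene(array(7, d), array(7, d), modality = "stack3d")
  riU <- relativeIntensities(uni, rois)
  expect_true(all(abs(riU$relativeIntensity - 1) < 1e-12))

  g <- array(1, d); g[syn] <- 2  # twice as bright synaptically, equal counts
  ri <- relativeIntensities(twoChannelScene(g, array(1, d),
                                            modality = "stack3d"), rois)
  expect_equal(riValue2 <- ri$relativeIntensity[
    ri$region == "synaptic" & ri$channel == "green"], 4 / 3)
  expect_equal(ri$relativeIntensity[
    ri$region == "extrasynaptic" & ri$channel == "green"], 2 / 3)

  withr::local_seed(8)
  for (i in 1:10) {
    gm <- array(runif(prod(d)) > 0.6, d)
    rm <- array(runif(prod(d)) > 0.4, d)
    if (!any(gm) && !any(rm)) next
    ro <- buildRoiSet(gm, rm)
    if (sum(ro@synaptic) < 1 || sum(ro@extrasynaptic) < 1) next
    sc <- twoChannelScene(array(runif(prod(d), 0, 100), d),
                          array(runif(prod(d), 0, 100), d),
                          modality = "stack3d")
    tab <- relativeIntensities(sc, ro)
    for (ch in c("green", "red")) {
      sub <- tab[tab$channel == ch, ]
      wm <- sum(sub$nVoxels * sub$relativeIntensity) / sum(sub$nVoxels)
      expect_lt(abs(wm - 1), 1e-9)
    }
  }
})

test_that("histogram-intersection thresholds land between the populations", {
  withr::local_seed(21)
  bg <- runif(5000, 0, 10)
  cell <- runif(5000, 100, 200)
  thr <- histogramIntersectionThreshold(cell, bg)
  expect_gt(thr, 10); expect_lt(thr, 100)

  bgN <- rnorm(4e5, 30, 12)
  cellN <- rnorm(4e5, 70, 12)
  thrN <- histogramIntersectionThreshold(cellN, bgN)
  binW <- diff(range(c(bgN, cellN))) / 256
  expect_lt(abs(thrN - 50), binW + 1e-9)

  expect_error(histogramIntersectionThreshold(bg, bg),
               class = "SynapseColoc_noThreshold")
  expect_error(histogramIntersectionThreshold(numeric(0), bg),
               class = "SynapseColoc_invalidParameter")
})

test_that("per-slice correlation averages eligible slices and skips others", {
  d <- c(6, 6, 4)
  base <- matrix(1:36, 6)
  g <- array(rep(base, 4), d)
  r <- g
  scId <- twoChannelScene(g, r, modality = "stack3d")
  roi <- array(TRUE, d)
  res <- perSlicePCC(scId, roi, 0, 0, minPixels = 10)
  expect_equal(unname(res$perSlice), rep(1, 4))
  expect_equal(res$cellMean, 1)
  expect_equal(res$nSlicesUsed, 4L)

  # alternating slices with correlation exactly 1 and exactly 0
  xa <- matrix(rep(c(1, 2, 1, 2), 9), 6)      # x pattern
  yb <- matrix(rep(c(1, 1, 2, 2), 9), 6)      # uncorrelated with xa
  g2 <- array(c(xa, xa, xa, xa), d)
  r2 <- array(c(xa, yb, xa, yb), d)
  res2 <- perSlicePCC(twoChannelScene(g2, r2, modality = "stack3d"),
                      roi, 0, 0, minPixels = 10)
  expect_equal(unname(res2$perSlice), c(1, 0, 1, 0))
  expect_equal(res2$cellMean, 0.5)

  # a slice below the gated-pixel minimum is skipped, not zero-filled
  roi2 <- roi; roi2[, , 2] <- FALSE; roi2[1:2, 1, 2] <- TRUE
  res3 <- perSlicePCC(scId, roi2, 0, 0, minPixels = 10)
  expect_true(is.na(res3$perSlice[2]))
  expect_equal(res3$nSlicesUsed, 3L)

  expect_error(perSlicePCC(scId, roi, 1e6, 1e6, minPixels = 10),
               class = "SynapseColoc_insufficientData")
})

test_that("uniform per-slice structure matches the volume-wise correlation", {
  withr::local_seed(14)
  sl <- matrix(runif(64, 0, 50), 8)
  sr <- sl + matrix(rnorm(64, 0, 5), 8)
  g <- array(rep(sl, 5), c(8, 8, 5))
  r <- array(rep(sr, 5), c(8, 8, 5))
  sc <- twoChannelScene(g, pmax(r, 0), modality = "stack3d")
  res <- perSlicePCC(sc, array(TRUE, c(8, 8, 5)), 0, 0, minPixels = 10)
  vol <- cor(as.vector(greenChannel(sc)[, , 1]),
             as.vector(redChannel(sc)[, , 1]))
  expect_equal(res$cellMean, vol, tolerance = 1e-12)
})

test_that("a noise-free perfect-copy stack scores a correlation of one", {
  tr <- sceneTruth("stack3d", colocFraction = 1, enrichmentGreen = 3,
                   enrichmentRed = 3, shotNoise = FALSE, readNoiseSd = 0,
                   seed = 6)
  m <- analyzeStackCell(generateStackScene(tr))
  expect_equal(m@pcc, 1)
  expect_gt(m@nSlicesUsed, 1L)
})

test_that("a synapse-excluded probe shows the expected intensity shift", {
  tr <- sceneTruth("stack3d", enrichmentRed = 0.5, colocFraction = 0,
                   seed = 9)
  m <- analyzeStackCell(generateStackScene(tr))
  expect_lt(riValue(m, "synaptic", "red"), 1)
  expect_gt(riValue(m, "extrasynaptic", "red"), 1)
  expect_gt(riValue(m, "synaptic", "green"), 1)
  expect_lt(riValue(m, "extrasynaptic", "green"), 1)
})

test_that("control slices run through the gated single-slice path", {
  tr <- smallTirfTruth(colocFraction = 0.5, seed = 13)
  m <- analyzeControlSlice(generateTirfScene(tr))
  expect_true(is.finite(m@pcc))
  expect_equal(m@nSlicesUsed, 1L)
})
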