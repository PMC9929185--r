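test_that("zero-signal scenes are pure background", {
  tr <- smallTirfTruth(photonsPerReceptor = 0, background = 5,
                       readNoiseSd = 0, shotNoise = FALSE, seed = 1)
  sc <- generateTirfScene(tr)
  expect_true(all(greenChannel(sc) == 5))
  expect_true(all(redChannel(sc) == 5))
})

test_that("full colocalization with matched enrichment copies the pattern", {
  tr <- smallTirfTruth(colocFraction = 1, enrichmentGreen = 3,
                       enrichmentRed = 3, shotNoise = FALSE,
                       readNoiseSd = 0, seed = 2)
  sc <- generateTirfScene(tr)
  expect_identical(greenChannel(sc), redChannel(sc))
  mask <- matrix(TRUE, nrow(greenChannel(sc)), ncol(greenChannel(sc)))
  expect_equal(pearsonCC(sc, mask), 1)
})

test_that("identical truth yields bit-identical scenes", {
  for (tr in list(smallTirfTruth(colocFraction = 0.5, seed = 7),
                  smallStackTruth(colocFraction = 0.5, seed = 7))) {
    a <- generateScene(tr)
    b <- generateScene(tr)
    expect_identical(greenChannel(a), greenChannel(b))
    expect_identical(redChannel(a), redChannel(b))
  }
})

test_that("expected signal scales linearly with the photon yield", {
  mk <- function(p) generateTirfScene(
    smallTirfTruth(photonsPerReceptor = p, background = 0, readNoiseSd = 0,
                   shotNoise = FALSE, seed = 5))
  ratio <- sum(greenChannel(mk(240))) / sum(greenChannel(mk(120)))
  expect_equal(ratio, 2, tolerance = 0.01)
})

test_that("a uniform probe has equal surface density on and off the synapse", {
  tr <- sceneTruth("stack3d", enrichmentRed = 1, shotNoise = FALSE,
                   readNoiseSd = 0, background = 0,
                   psfSigmaLateral = 1e-6, psfSigmaAxial = 1e-6, seed = 4)
  sc <- generateStackScene(tr)
  # a margin separates the regions; dilating each mask by one voxel makes
  # the capture complete against voxel-rounding at region boundaries
  tm <- truthMasks(tr, margin = 0.15)
  synM <- SynapseColoc:::.dilateBox(tm$synaptic, c(1, 1, 1))
  extM <- SynapseColoc:::.dilateBox(tm$extrasynaptic, c(1, 1, 1))
  expect_false(any(synM & extM))
  redDensSyn <- sum(redChannel(sc)[synM]) / tm$areas[["synaptic"]]
  redDensExt <- sum(redChannel(sc)[extM]) / tm$areas[["extrasynaptic"]]
  expect_equal(redDensSyn / redDensExt, 1, tolerance = 0.05)
  # and the green reference recovers its generated enrichment by construction
  gS <- sum(greenChannel(sc)[synM]) / tm$areas[["synaptic"]]
  gE <- sum(greenChannel(sc)[extM]) / tm$areas[["extrasynaptic"]]
  expect_equal(gS / gE, 3, tolerance = 0.1)
})

test_that("cohorts are reproducible and condition-labelled", {
  tr <- smallTirfTruth(condition = "A")
  a <- generateCohort(tr, 3, seed = 7)
  b <- generateCohort(tr, 3, seed = 7)
  expect_length(a, 3L)
  for (i in 1:3)
    expect_identical(greenChannel(a[[i]]), greenChannel(b[[i]]))
  trio <- generateCohort(synapseConditions("tirf2d"), 4, seed = 1)
  expect_length(trio, 12L)
  conds <- vapply(trio, function(s) sceneTruthOf(s)@condition, "")
  expect_equal(as.integer(table(conds)[c("CAR_CAR", "CAR_TCR", "CAR_TFR")]),
               rep(4L, 3))
})

test_that("the master seed changes noise but not per-cell truth parameters", {
  a <- generateCohort(smallTirfTruth(), 3, seed = 1)
  b <- generateCohort(smallTirfTruth(), 3, seed = 2)
  for (i in 1:3) {
    ta <- sceneTruthOf(a[[i]]); tb <- sceneTruthOf(b[[i]])
    expect_identical(ta@cellRadius, tb@cellRadius)
    expect_identical(ta@enrichmentGreen, tb@enrichmentGreen)
    expect_identical(ta@enrichmentRed, tb@enrichmentRed)
    expect_false(identical(greenChannel(a[[i]]), greenChannel(b[[i]])))
  }
})

test_that("invalid generator parameters are rejected", {
  expect_error(smallTirfTruth(colocFraction = 1.2), "colocFraction")
  expect_error(smallTirfTruth(cellRadius = 0), "cellRadius")
  expect_error(sceneTruth("stack3d", capAngle = pi), "capAngle")
  expect_error(sceneTruth("stack3d", enrichmentRed = -1), "enrichment")
  expect_error(generateTirfScene(sceneTruth("stack3d")),
               class = "SynapseColoc_invalidParameter")
  expect_error(generateStackScene(sceneTruth("tirf2d")),
               class = "SynapseColoc_invalidParameter")
  expect_error(generateCohort(list(), 3),
               class = "SynapseColoc_invalidParameter")
  expect_error(generateCohort(smallTirfTruth(), 0),
               class = "SynapseColoc_invalidParameter")
})

test_that("measured synaptic correlation increases with the shared fraction", {
  means <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(rho) {
    cells <- generateCohort(smallStackTruth(colocFraction = rho), 10,
                            seed = 42)
    mean(vapply(cells, function(s) analyzeStackCell(s)@pcc, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})
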