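#' Construct the ground truth for a synthetic scene
#'
#' Fills a [SceneTruth-class] with the study defaults: a 128x128 px TIRF frame
#' at 160 nm pixels, or a 96x96x60 voxel stack at 100 nm lateral / 0.23 um
#' axial sampling; Gaussian PSF sigmas derived from 120 nm lateral / 350 nm
#' axial FWHM resolution (sigma = FWHM / 2.355); a synaptic enrichment of 3
#' for the green reference receptor; and EMCCD-scale photon statistics.
#' Receptor surface density and photon yield are free parameters of the
#' simulation (no measured values exist for them); the defaults are
#' physiologically plausible mid-range choices documented in the methods
#' vignette.
#'
#' @param modality \code{"tirf2d"} or \code{"stack3d"}.
#' @param gridDim grid shape; defaults depend on modality.
#' @param pixelSizeLateral lateral pixel size, nm (160 TIRF / 100 stack).
#' @param zStep axial step, um.
#' @param cellRadius cell or contact-disc radius, um.
#' @param capAngle synaptic cap half-angle, radians, in (0, pi).
#' @param enrichmentGreen,enrichmentRed synaptic/extrasynaptic density ratio.
#' @param colocFraction fraction of red signal copied from the green pattern.
#' @param baselineDensity extrasynaptic receptor density, molecules/um^2.
#'   Default 20 for stacks (of the order of 1e4 receptors over a lymphocyte
#'   surface, resolved as sparse labels by the sectioning optics) and 100
#'   for TIRF frames, whose evanescent excitation integrates the membrane
#'   together with the sub-membrane receptor pool into one dense footprint.
#' @param photonsPerReceptor detected photons per molecule.
#' @param background camera background, counts/pixel (default 10 for raw
#'   EMCCD TIRF frames, 2 for deconvolution-processed stacks).
#' @param readNoiseSd Gaussian read noise SD, counts (default 3 TIRF /
#'   1 stack).
#' @param psfSigmaLateral,psfSigmaAxial PSF sigma, nm.
#' @param tirfContrast evanescent-field attenuation outside the contact disc.
#' @param shotNoise logical; \code{FALSE} yields noise-free expected images.
#' @param seed integer RNG seed.
#' @param condition condition label.
#' @return a validated [SceneTruth-class]
#' @examples
#' tr <- sceneTruth("tirf2d", colocFraction = 0.9, seed = 7)
#' tr
#' @export
sceneTruth <- function(modality = c("stack3d", "tirf2d"),
                       gridDim = NULL,
                       pixelSizeLateral = NULL,
                       zStep = 0.23,
                       cellRadius = NULL,
                       capAngle = 1.1,
                       enrichmentGreen = 3,
                       enrichmentRed = 1,
                       colocFraction = 0,
                       baselineDensity = NULL,
                       photonsPerReceptor = 120,
                       background = NULL,
                       readNoiseSd = NULL,
                       psfSigmaLateral = 120 / 2.355,
                       psfSigmaAxial = 350 / 2.355,
                       tirfContrast = 0.15,
                       shotNoise = TRUE,
                       seed = 1L,
                       condition = "scene") {
  modality <- match.arg(modality)
  if (is.null(gridDim))
    gridDim <- if (modality == "tirf2d") c(128L, 128L) else c(96L, 96L, 60L)
  if (is.null(pixelSizeLateral))
    pixelSizeLateral <- if (modality == "tirf2d") 160 else 100
  if (is.null(cellRadius))
    cellRadius <- if (modality == "tirf2d") 4 else 3.2
  if (is.null(baselineDensity))
    baselineDensity <- if (modality == "tirf2d") 100 else 20
  if (is.null(background))
    background <- if (modality == "tirf2d") 10 else 2
  if (is.null(readNoiseSd))
    readNoiseSd <- if (modality == "tirf2d") 3 else 1
  new("SceneTruth", modality = modality, gridDim = as.integer(gridDim),
      pixelSizeLateral = pixelSizeLateral, zStep = zStep,
      cellRadius = cellRadius, capAngle = capAngle,
      enrichmentGreen = enrichmentGreen, enrichmentRed = enrichmentRed,
      colocFraction = colocFraction, baselineDensity = baselineDensity,
      photonsPerReceptor = photonsPerReceptor, background = background,
      readNoiseSd = readNoiseSd, psfSigmaLateral = psfSigmaLateral,
      psfSigmaAxial = psfSigmaAxial, tirfContrast = tirfContrast,
      shotNoise = shotNoise, seed = as.integer(seed), condition = condition)
}

# Bin continuous (row, col[, slice]) molecule positions into a count grid.
.binPositions <- function(rows, cols, slices = NULL, d) {
  i <- round(rows); j <- round(cols)
  ok <- i >= 1 & i <= d[1L] & j >= 1 & j <= d[2L]
  if (is.null(slices)) {
    lin <- i[ok] + (j[ok] - 1) * d[1L]
  } else {
    k <- round(slices)
    ok <- ok & k >= 1 & k <= d[3L]
    lin <- i[ok] + (j[ok] - 1) * d[1L] + (k[ok] - 1) * d[1L] * d[2L]
  }
  array(tabulate(lin, prod(d)), d)
}

# Spatial Poisson point process on a 2D field with a contact disc:
# density densIn inside the disc, densOut outside. Lengths in um.
.sampleDiscProcess <- function(d, pxUm, radiusUm, densIn, densOut) {
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
  areaDisc <- pi * radiusUm^2
  areaField <- prod(d) * pxUm^2
  nIn <- stats::rpois(1L, densIn * areaDisc)
  rad <- radiusUm * sqrt(stats::runif(nIn))
  ang <- stats::runif(nIn, 0, 2 * pi)
  rIn <- cy + rad * sin(ang) / pxUm
  cIn <- cx + rad * cos(ang) / pxUm
  nOut <- stats::rpois(1L, densOut * max(0, areaField - areaDisc))
  rOut <- numeric(0); cOut <- numeric(0)
  while (length(rOut) < nOut) {
    m <- max(64L, 2L * (nOut - length(rOut)))
    ry <- stats::runif(m, 0.5, d[1L] + 0.5)
    cxs <- stats::runif(m, 0.5, d[2L] + 0.5)
    keep <- ((ry - cy)^2 + (cxs - cx)^2) * pxUm^2 > radiusUm^2
    rOut <- c(rOut, ry[keep]); cOut <- c(cOut, cxs[keep])
  }
  rOut <- rOut[seq_len(nOut)]; cOut <- cOut[seq_len(nOut)]
  .binPositions(c(rIn, rOut), c(cIn, cOut), NULL, d)
}

# Poisson point process on the membrane of a cell contacting a target below:
# a sphere truncated at the contact plane (polar angle capAngle from the -z
# axis), whose flat circular face is the synaptic interface. Receptor density
# is densCap on the contact disc and densRest on the remaining sphere.
.sampleMembraneProcess <- function(d, pxUm, zUm, radiusUm, capAngle,
                                   densCap, densRest) {
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2; cz <- (d[3L] + 1) / 2
  u0 <- cos(capAngle)
  discR <- radiusUm * sin(capAngle)
  areaDisc <- pi * discR^2
  areaRest <- 4 * pi * radiusUm^2 - 2 * pi * radiusUm^2 * (1 - u0)
  nDisc <- stats::rpois(1L, densCap * areaDisc)
  rad <- discR * sqrt(stats::runif(nDisc))
  angD <- stats::runif(nDisc, 0, 2 * pi)
  rowsD <- cy + rad * sin(angD) / pxUm
  colsD <- cx + rad * cos(angD) / pxUm
  slicesD <- rep(cz - radiusUm * u0 / zUm, nDisc)
  nRest <- stats::rpois(1L, densRest * areaRest)
  u <- stats::runif(nRest, -1, u0)
  psi <- stats::runif(nRest, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - u^2))
  rowsS <- cy + radiusUm * s * sin(psi) / pxUm
  colsS <- cx + radiusUm * s * cos(psi) / pxUm
  slicesS <- cz - radiusUm * u / zUm
  .binPositions(c(rowsD, rowsS), c(colsD, colsS), c(slicesD, slicesS), d)
}

# Per-voxel map: TRUE where the voxel direction from the cell centre lies
# within the synaptic cap (used to rescale the shared red pattern).
.capRegionMap3D <- function(d, pxUm, zUm, capAngle) {
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2; cz <- (d[3L] + 1) / 2
  dy <- (seq_len(d[1L]) - cy) * pxUm
  dx <- (seq_len(d[2L]) - cx) * pxUm
  dz <- (cz - seq_len(d[3L])) * zUm  # + towards the cap (low z)
  dy2 <- array(rep(dy^2, times = d[2L] * d[3L]), d)
  dx2 <- array(rep(rep(dx^2, each = d[1L]), times = d[3L]), d)
  dzA <- array(rep(dz, each = d[1L] * d[2L]), d)
  r <- sqrt(dy2 + dx2 + dzA^2)
  u <- ifelse(r > 0, dzA / r, 0)
  u > cos(capAngle)
}

.discRegionMap2D <- function(d, pxUm, radiusUm) {
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2
  dy <- (seq_len(d[1L]) - cy) * pxUm
  dx <- (seq_len(d[2L]) - cx) * pxUm
  outer(dy^2, dx^2, `+`) <= radiusUm^2
}

# Shared-pattern weight inside the synaptic region: the red copy of the green
# pattern is rescaled so its net synaptic enrichment equals enrichmentRed.
.sharedWeight <- function(truth) {
  if (truth@enrichmentGreen > 0) truth@enrichmentRed / truth@enrichmentGreen
  else 0
}

# Detection + noise applied to an expected molecular-photon image.
.detect <- function(expected, truth) {
  lambda <- expected + truth@background
  img <- if (truth@shotNoise) {
    array(stats::rpois(length(lambda), lambda), dim(lambda))
  } else lambda
  if (truth@readNoiseSd > 0)
    img <- img + stats::rnorm(length(img), 0, truth@readNoiseSd)
  array(round(pmax(img, 0)), dim(img))
}

#' Generate a synthetic TIRF frame
#'
#' Realizes a 2D two-channel contact scene: receptor positions are drawn as a
#' spatial Poisson point process with density \code{enrichmentGreen} (green)
#' or \code{enrichmentRed} (red) times the baseline inside a disc-shaped
#' contact footprint; a fraction \code{colocFraction} of the red pattern is
#' copied from the green molecular pattern (rescaled by
#' \code{enrichmentRed / enrichmentGreen} inside the disc) and the remainder
#' drawn independently. Membrane outside the footprint is attenuated by
#' \code{tirfContrast} (evanescent-field decay). Both channels are convolved
#' with the lateral Gaussian PSF, then Poisson shot noise, camera background
#' and Gaussian read noise are applied and intensities are quantized to
#' non-negative integer counts.
#'
#' @param truth a [SceneTruth-class] with \code{modality == "tirf2d"}.
#' @return a [TwoChannelScene-class] with the truth embedded
#' @examples
#' sc <- generateTirfScene(sceneTruth("tirf2d", colocFraction = 1,
#'                                    enrichmentRed = 3, seed = 2))
#' sc
#' @export
generateTirfScene <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  validObject(truth)
  if (truth@modality != "tirf2d")
    scStop("generateTirfScene requires modality 'tirf2d'", "invalidParameter")
  d <- truth@gridDim
  pxUm <- truth@pixelSizeLateral / 1000
  withr::with_seed(truth@seed, {
    dens <- truth@baselineDensity
    S <- .sampleDiscProcess(d, pxUm, truth@cellRadius,
                            dens * truth@enrichmentGreen, dens)
    Rind <- .sampleDiscProcess(d, pxUm, truth@cellRadius,
                               dens * truth@enrichmentRed, dens)
    disc <- .discRegionMap2D(d, pxUm, truth@cellRadius)
    w <- ifelse(disc, .sharedWeight(truth), 1)
    rho <- truth@colocFraction
    redPattern <- rho * w * S + (1 - rho) * Rind
    contrast <- ifelse(disc, 1, truth@tirfContrast)
    sig <- truth@psfSigmaLateral / truth@pixelSizeLateral
    eg <- .gaussianBlur(S * truth@photonsPerReceptor * contrast, c(sig, sig))
    er <- .gaussianBlur(redPattern * truth@photonsPerReceptor * contrast,
                        c(sig, sig))
    g <- .detect(eg, truth)
    r <- .detect(er, truth)
  })
  new("TwoChannelScene", green = g, red = r,
      pixelSizeLateral = truth@pixelSizeLateral, zStep = truth@zStep,
      modality = "tirf2d", truth = truth)
}

#' Generate a synthetic 3D stack
#'
#' Realizes a confocal-like z-stack of one cell in contact with a target
#' below: the membrane is a sphere truncated at the contact plane (polar
#' angle \code{capAngle} from the downward axis), whose flat circular face
#' is the synaptic interface. Receptors are Poisson-distributed on this
#' surface; synaptic density is \code{enrichmentGreen} (green) or
#' \code{enrichmentRed} (red) times the extrasynaptic baseline.
#' A fraction \code{colocFraction} of the red pattern is copied from the
#' green molecular pattern (rescaled inside the cap so the red net enrichment
#' stays \code{enrichmentRed}); the rest is an independent point process.
#' Channels are convolved with the anisotropic Gaussian PSF, sampled at
#' (pixel, pixel, z-step) voxels, and carry Poisson shot noise, background
#' and read noise as integer counts.
#'
#' @param truth a [SceneTruth-class] with \code{modality == "stack3d"}.
#' @return a [TwoChannelScene-class] with the truth embedded
#' @export
generateStackScene <- function(truth) {
  stopifnot(is(truth, "SceneTruth"))
  validObject(truth)
  if (truth@modality != "stack3d")
    scStop("generateStackScene requires modality 'stack3d'", "invalidParameter")
  d <- truth@gridDim
  pxUm <- truth@pixelSizeLateral / 1000
  zUm <- truth@zStep
  withr::with_seed(truth@seed, {
    dens <- truth@baselineDensity
    S <- .sampleMembraneProcess(d, pxUm, zUm, truth@cellRadius,
                                truth@capAngle,
                                dens * truth@enrichmentGreen, dens)
    Rind <- .sampleMembraneProcess(d, pxUm, zUm, truth@cellRadius,
                                   truth@capAngle,
                                   dens * truth@enrichmentRed, dens)
    cap <- .capRegionMap3D(d, pxUm, zUm, truth@capAngle)
    w <- ifelse(cap, .sharedWeight(truth), 1)
    rho <- truth@colocFraction
    redPattern <- rho * w * S + (1 - rho) * Rind
    sigL <- truth@psfSigmaLateral / truth@pixelSizeLateral
    sigA <- truth@psfSigmaAxial / (truth@zStep * 1000)
    eg <- .gaussianBlur(S * truth@photonsPerReceptor, c(sigL, sigL, sigA))
    er <- .gaussianBlur(redPattern * truth@photonsPerReceptor,
                        c(sigL, sigL, sigA))
    g <- .detect(eg, truth)
    r <- .detect(er, truth)
  })
  new("TwoChannelScene", green = g, red = r,
      pixelSizeLateral = truth@pixelSizeLateral, zStep = truth@zStep,
      modality = "stack3d", truth = truth)
}

#' Generate a scene regardless of modality
#'
#' Dispatches to [generateTirfScene()] or [generateStackScene()].
#' @param truth a [SceneTruth-class].
#' @return a [TwoChannelScene-class]
#' @export
generateScene <- function(truth) {
  if (truth@modality == "tirf2d") generateTirfScene(truth)
  else generateStackScene(truth)
}

#' Ground-truth geometry masks for a synthetic scene
#'
#' Voxel/pixel masks of the true synaptic and extrasynaptic regions implied
#' by a [SceneTruth-class], for parameter-recovery tests (e.g. Dice overlap
#' of a segmented ROI with the true contact). For stacks the synaptic truth
#' is a slab around the flat contact disc and the extrasynaptic truth the
#' spherical shell above it (voxels within ~half an axial step of the
#' surface); an angular \code{margin} (radians) can exclude the junction
#' where the PSF mixes the two regions.
#'
#' @param truth a [SceneTruth-class].
#' @param margin angular margin in radians around the contact edge (3D only).
#' @return for \code{stack3d}: list with logical arrays \code{synaptic},
#'   \code{extrasynaptic}, \code{membrane}, plus \code{areas} (um^2 of the
#'   true synaptic/extrasynaptic membrane); for \code{tirf2d}: list with
#'   \code{contact} (the disc footprint).
#' @export
truthMasks <- function(truth, margin = 0) {
  d <- truth@gridDim
  pxUm <- truth@pixelSizeLateral / 1000
  if (truth@modality == "tirf2d") {
    return(list(contact = .discRegionMap2D(d, pxUm, truth@cellRadius)))
  }
  zUm <- truth@zStep
  R <- truth@cellRadius
  cy <- (d[1L] + 1) / 2; cx <- (d[2L] + 1) / 2; cz <- (d[3L] + 1) / 2
  dy <- (seq_len(d[1L]) - cy) * pxUm
  dx <- (seq_len(d[2L]) - cx) * pxUm
  dz <- (cz - seq_len(d[3L])) * zUm
  dy2 <- array(rep(dy^2, times = d[2L] * d[3L]), d)
  dx2 <- array(rep(rep(dx^2, each = d[1L]), times = d[3L]), d)
  dzA <- array(rep(dz, each = d[1L] * d[2L]), d)
  rho2 <- dy2 + dx2                       # squared lateral distance to axis
  r <- sqrt(rho2 + dzA^2)
  u0 <- cos(truth@capAngle)
  discR <- R * sin(truth@capAngle)
  # contact disc: slab of ~1 z-step around the truncation plane
  syn <- abs(dzA - R * u0) <= 0.6 * zUm &
    rho2 <= (R * sin(truth@capAngle - margin))^2
  u <- ifelse(r > 0, dzA / r, 0)
  ang <- acos(pmin(pmax(u, -1), 1))
  extra <- abs(r - R) <= 0.6 * zUm & ang > (truth@capAngle + margin)
  extra <- extra & !syn
  list(
    synaptic = syn,
    extrasynaptic = extra,
    membrane = syn | extra,
    # membrane areas of the margin-restricted regions, um^2
    areas = c(
      synaptic = pi * (R * sin(truth@capAngle - margin))^2,
      extrasynaptic = 4 * pi * R^2 -
        2 * pi * R^2 * (1 - cos(truth@capAngle + margin)))
  )
}

#' The three probe conditions of the study design
#'
#' Truth templates for the three-probe study design: an identical-target
#' probe (\code{CAR_CAR}: red strongly copies the green pattern), a
#' synapse-excluded probe (\code{CAR_TCR}: red depleted from the cap,
#' independent of green), and a uniformly distributed control
#' (\code{CAR_TFR}: red uniform, independent).
#'
#' @param modality \code{"stack3d"} or \code{"tirf2d"}.
#' @param ... further arguments passed to [sceneTruth()] (applied to all
#'   three conditions).
#' @return named list of three [SceneTruth-class] objects
#' @examples
#' names(synapseConditions("tirf2d"))
#' @export
synapseConditions <- function(modality = c("stack3d", "tirf2d"), ...) {
  modality <- match.arg(modality)
  list(
    CAR_CAR = sceneTruth(modality, enrichmentRed = 3, colocFraction = 0.9,
                         condition = "CAR_CAR", ...),
    CAR_TCR = sceneTruth(modality, enrichmentRed = 0.5, colocFraction = 0,
                         condition = "CAR_TCR", ...),
    CAR_TFR = sceneTruth(modality, enrichmentRed = 1, colocFraction = 0,
                         condition = "CAR_TFR", ...)
  )
}

#' Generate a cohort of scenes with cell-to-cell variability
#'
#' Produces \code{nCellsPerCondition} scenes per truth template. Each cell
#' receives a deterministic child seed derived from the master seed by a
#' fixed counter scheme, plus mild biological jitter (log-normal, 8% SD) on
#' cell radius and enrichment factors. The jitter sequence depends only on
#' the cell index, so two cohorts generated under different master seeds
#' share identical per-cell truth parameters and differ only in the noise
#' realization.
#'
#' @param truths a [SceneTruth-class] or (named) list of them, one per
#'   condition.
#' @param nCellsPerCondition cells per condition (>= 1).
#' @param seed master seed.
#' @param jitterSd SD of the log-normal jitter (0 disables it).
#' @return list of [TwoChannelScene-class], each with its per-cell truth
#' @examples
#' sc <- generateCohort(synapseConditions("tirf2d"), 2, seed = 7)
#' length(sc)
#' @export
generateCohort <- function(truths, nCellsPerCondition, seed = 1L,
                           jitterSd = 0.08) {
  if (is(truths, "SceneTruth")) truths <- list(truths)
  if (!length(truths))
    scStop("empty truth list", "invalidParameter")
  if (nCellsPerCondition < 1L)
    scStop("nCellsPerCondition must be >= 1", "invalidParameter")
  scenes <- vector("list", length(truths) * nCellsPerCondition)
  idx <- 0L
  for (ci in seq_along(truths)) {
    tr0 <- truths[[ci]]
    stopifnot(is(tr0, "SceneTruth"))
    for (j in seq_len(nCellsPerCondition)) {
      idx <- idx + 1L
      tr <- tr0
      if (jitterSd > 0) {
        jit <- withr::with_seed(jitterSeed(idx),
                                stats::rnorm(3L, 0, jitterSd))
        tr@cellRadius <- tr@cellRadius * exp(jit[1L])
        tr@enrichmentGreen <- tr@enrichmentGreen * exp(jit[2L])
        tr@enrichmentRed <- tr@enrichmentRed * exp(jit[3L])
      }
      tr@seed <- deriveSeed(seed, idx)
      tr@condition <- tr0@condition
      sc <- generateScene(tr)
      attr(sc, "cellId") <- sprintf("%s_%02d", tr0@condition, j)
      scenes[[idx]] <- sc
    }
  }
  scenes
}
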