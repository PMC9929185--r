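#' @import methods
NULL

#' Ground truth for a synthetic two-channel scene
#'
#' Generative parameters of one synthetic cell contact. The green channel
#' models a reference receptor (a GFP-tagged CAR) enriched in the synaptic
#' region; the red channel models a probe that either copies the green
#' molecular pattern (colocalized), is depleted from the synapse
#' (\code{enrichmentRed < 1}), or distributes uniformly
#' (\code{enrichmentRed = 1}).
#'
#' @slot modality \code{"tirf2d"} (single contact-plane frame) or
#'   \code{"stack3d"} (confocal-like z-stack).
#' @slot gridDim integer vector, \code{c(rows, cols)} or
#'   \code{c(rows, cols, slices)}.
#' @slot pixelSizeLateral lateral pixel size in nm.
#' @slot zStep axial step in micrometers (stacks only).
#' @slot cellRadius cell (or contact disc) radius in micrometers.
#' @slot capAngle half-opening angle (radians) of the synaptic cap on the
#'   membrane sphere; must lie in (0, pi).
#' @slot enrichmentGreen,enrichmentRed receptor surface density in the
#'   synaptic region relative to the extrasynaptic membrane (>= 0; < 1 encodes
#'   exclusion, 1 uniform, > 1 accumulation).
#' @slot colocFraction fraction in [0, 1] of the red signal copied from the
#'   green molecular pattern (the colocalization knob).
#' @slot baselineDensity extrasynaptic receptor density, molecules per um^2.
#' @slot photonsPerReceptor expected detected photons per molecule.
#' @slot background camera background, counts per pixel.
#' @slot readNoiseSd Gaussian read noise SD, counts.
#' @slot psfSigmaLateral,psfSigmaAxial Gaussian PSF sigma in nm
#'   (FWHM / 2.355 of the stated optical resolution).
#' @slot tirfContrast detection attenuation for membrane outside the TIRF
#'   contact footprint (evanescent-field decay), in (0, 1].
#' @slot shotNoise logical; disable to obtain noise-free expected images
#'   (read noise is controlled separately by \code{readNoiseSd}).
#' @slot seed integer RNG seed; identical truth implies bit-identical scenes.
#' @slot condition free-text condition label.
#' @seealso [sceneTruth()], [generateTirfScene()], [generateStackScene()]
#' @export
setClass("SceneTruth",
  representation(
    modality = "character",
    gridDim = "integer",
    pixelSizeLateral = "numeric",
    zStep = "numeric",
    cellRadius = "numeric",
    capAngle = "numeric",
    enrichmentGreen = "numeric",
    enrichmentRed = "numeric",
    colocFraction = "numeric",
    baselineDensity = "numeric",
    photonsPerReceptor = "numeric",
    background = "numeric",
    readNoiseSd = "numeric",
    psfSigmaLateral = "numeric",
    psfSigmaAxial = "numeric",
    tirfContrast = "numeric",
    shotNoise = "logical",
    seed = "integer",
    condition = "character"
  )
)

setValidity("SceneTruth", function(object) {
  msg <- character()
  if (!object@modality %in% c("tirf2d", "stack3d"))
    msg <- c(msg, "modality must be 'tirf2d' or 'stack3d'")
  nd <- if (identical(object@modality, "tirf2d")) 2L else 3L
  if (length(object@gridDim) != nd || any(object@gridDim <= 0L))
    msg <- c(msg, sprintf("gridDim must be %d positive integers", nd))
  for (s in c("pixelSizeLateral", "zStep", "cellRadius"))
    if (slot(object, s) <= 0) msg <- c(msg, paste(s, "must be > 0"))
  if (object@capAngle <= 0 || object@capAngle >= pi)
    msg <- c(msg, "capAngle must lie in (0, pi)")
  if (object@enrichmentGreen < 0 || object@enrichmentRed < 0)
    msg <- c(msg, "enrichment factors must be >= 0")
  if (object@colocFraction < 0 || object@colocFraction > 1)
    msg <- c(msg, "colocFraction must lie in [0, 1]")
  if (object@baselineDensity < 0 || object@photonsPerReceptor < 0 ||
      object@background < 0 || object@readNoiseSd < 0)
    msg <- c(msg, "densities, photon yield, background and read noise must be >= 0")
  if (object@psfSigmaLateral <= 0 || object@psfSigmaAxial <= 0)
    msg <- c(msg, "PSF sigmas must be > 0")
  if (object@tirfContrast <= 0 || object@tirfContrast > 1)
    msg <- c(msg, "tirfContrast must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setClassUnion("SceneTruthOrNULL", c("SceneTruth", "NULL"))

#' Two-channel fluorescence scene
#'
#' A paired green/red intensity grid (2D frame or 3D stack) with physical
#' calibration, the unit of analysis (one cell contact). Intensities are
#' non-negative camera counts. Synthetic scenes carry their [SceneTruth-class]
#' for parameter-recovery tests; scenes read from disk may have
#' \code{truth = NULL}.
#'
#' @slot green,red numeric arrays of identical dimension, finite and >= 0.
#' @slot pixelSizeLateral lateral pixel size, nm.
#' @slot zStep axial step, micrometers (ignored for 2D frames).
#' @slot modality \code{"tirf2d"} or \code{"stack3d"}.
#' @slot truth optional [SceneTruth-class].
#' @seealso [twoChannelScene()], [greenChannel()], [redChannel()]
#' @export
setClass("TwoChannelScene",
  representation(
    green = "array",
    red = "array",
    pixelSizeLateral = "numeric",
    zStep = "numeric",
    modality = "character",
    truth = "SceneTruthOrNULL"
  )
)

setValidity("TwoChannelScene", function(object) {
  msg <- character()
  if (!identical(dim(object@green), dim(object@red)))
    msg <- c(msg, "green and red channels must have identical dimensions")
  if (anyNA(object@green) || anyNA(object@red) ||
      any(!is.finite(object@green)) || any(!is.finite(object@red)))
    msg <- c(msg, "intensities must be finite")
  else if (min(object@green) < 0 || min(object@red) < 0)
    msg <- c(msg, "intensities must be >= 0")
  if (!object@modality %in% c("tirf2d", "stack3d"))
    msg <- c(msg, "modality must be 'tirf2d' or 'stack3d'")
  nd <- length(dim(object@green))
  if (identical(object@modality, "tirf2d") && nd != 2L)
    msg <- c(msg, "tirf2d scenes must be 2D")
  if (identical(object@modality, "stack3d") && nd != 3L)
    msg <- c(msg, "stack3d scenes must be 3D")
  if (object@pixelSizeLateral <= 0 || object@zStep <= 0)
    msg <- c(msg, "calibration lengths must be > 0")
  if (length(msg)) msg else TRUE
})

#' Intensity threshold specification
#'
#' How a gating or segmentation threshold is obtained: a user-supplied value,
#' Otsu's method on the data at hand, or the intersection of cell/background
#' intensity histograms (which requires explicit samples, see
#' [histogramIntersectionThreshold()]).
#'
#' @slot method one of \code{"user"}, \code{"otsu"},
#'   \code{"histogram_intersect"}.
#' @slot value numeric threshold, required (and >= 0) iff
#'   \code{method == "user"}.
#' @seealso [thresholdSpec()]
#' @export
setClass("ThresholdSpec",
  representation(method = "character", value = "numeric")
)

setValidity("ThresholdSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("user", "otsu", "histogram_intersect"))
    msg <- c(msg, "method must be 'user', 'otsu' or 'histogram_intersect'")
  if (identical(object@method, "user")) {
    if (length(object@value) != 1L || is.na(object@value))
      msg <- c(msg, "method 'user' requires a threshold value")
    else if (object@value < 0)
      msg <- c(msg, "threshold value must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Synaptic / extrasynaptic / whole-cell ROI triple
#'
#' Boolean voxel masks of the synaptic contact region (anchored on the green
#' channel), the extrasynaptic membrane (anchored on the red channel with
#' synaptic voxels removed), and the whole cell membrane (their union). The
#' class enforces that synaptic and extrasynaptic masks are disjoint and that
#' the whole-cell mask equals their exact union.
#'
#' @slot synaptic,extrasynaptic,wholeCell logical arrays of equal dimension.
#' @seealso [buildRoiSet()]
#' @export
setClass("RoiSet3D",
  representation(
    synaptic = "array",
    extrasynaptic = "array",
    wholeCell = "array"
  )
)

setValidity("RoiSet3D", function(object) {
  msg <- character()
  if (!is.logical(object@synaptic) || !is.logical(object@extrasynaptic) ||
      !is.logical(object@wholeCell))
    msg <- c(msg, "masks must be logical arrays")
  else {
    if (!identical(dim(object@synaptic), dim(object@extrasynaptic)) ||
        !identical(dim(object@synaptic), dim(object@wholeCell)))
      msg <- c(msg, "masks must have identical dimensions")
    else {
      if (any(object@synaptic & object@extrasynaptic))
        msg <- c(msg, "synaptic and extrasynaptic masks must be disjoint")
      if (!identical(as.vector(object@wholeCell),
                     as.vector(object@synaptic | object@extrasynaptic)))
        msg <- c(msg, "wholeCell must equal the union of synaptic and extrasynaptic")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-cell measurement
#'
#' Outputs of the per-cell analysis: contact area (2D), Pearson correlation
#' (overall for TIRF; per-slice mean within the synaptic and extrasynaptic ROI
#' for stacks), pixel counts, relative intensities, and QC flags. An undefined
#' correlation (zero variance or empty ROI) is reported as \code{NA} plus a
#' flag, never as 0.
#'
#' @slot cellId,condition,modality character scalars.
#' @slot contactArea contact area in um^2 (2D; \code{NA} for stacks).
#' @slot pcc Pearson correlation (TIRF: over the gated contact ROI; stacks:
#'   per-slice mean over the synaptic ROI).
#' @slot pccExtrasynaptic per-slice mean PCC over the extrasynaptic ROI
#'   (stacks only).
#' @slot nPixelsUsed pixels/voxels entering the correlation.
#' @slot nSlicesUsed slices with enough gated pixels (stacks only).
#' @slot perSlicePcc named list of per-slice PCC vectors (stacks only).
#' @slot relativeIntensities data.frame with columns region, channel,
#'   nVoxels, meanIntensity, relativeIntensity (stacks only).
#' @slot flags character vector of QC flags (e.g. \code{"undefined_pcc"},
#'   \code{"synaptic_touches_border"}, \code{"empty_extrasynaptic"}).
#' @seealso [analyzeTirfCell()], [analyzeStackCell()]
#' @export
setClass("CellMeasurement",
  representation(
    cellId = "character",
    condition = "character",
    modality = "character",
    contactArea = "numeric",
    pcc = "numeric",
    pccExtrasynaptic = "numeric",
    nPixelsUsed = "integer",
    nSlicesUsed = "integer",
    perSlicePcc = "list",
    relativeIntensities = "data.frame",
    flags = "character"
  ),
  prototype(
    contactArea = NA_real_, pcc = NA_real_, pccExtrasynaptic = NA_real_,
    nPixelsUsed = 0L, nSlicesUsed = NA_integer_,
    perSlicePcc = list(), relativeIntensities = data.frame(),
    flags = character()
  )
)
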