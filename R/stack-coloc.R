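# 3D stack analysis: segmentation, relative intensities, gated per-slice PCC.

#' Segment a 3D region of interest by intensity thresholding
#'
#' Thresholds a (mean-filtered) single-channel stack and keeps the largest
#' 26-connected component. With the default Otsu specification a two-level
#' (three-class) Otsu is computed on the pooled voxel histogram — a single
#' two-class split is unstable here because the stack histogram has three
#' populations (background, membrane halo, bright membrane) whose candidate
#' splits score almost identically; the three-class fit resolves this
#' deterministically. The two anchors then use the levels as follows:
#' \describe{
#'   \item{synaptic}{voxels above the \emph{upper} threshold (the bright
#'     receptor accumulation in the green channel). An optional \code{zRange}
#'     restricts the candidates to the slices around the contact plane before
#'     the largest component is taken: the synaptic and extrasynaptic
#'     membrane form one connected surface after smoothing, so membrane far
#'     above the contact would otherwise merge into the synaptic component.
#'     This bounded window is the automated counterpart of verifying synaptic
#'     ROIs against the visible extent of the contact region.}
#'   \item{extrasynaptic}{foreground voxels (above the \emph{lower}
#'     threshold) lying within \code{coreMargin} voxels of the bright
#'     membrane core (above the upper threshold). Signal genuinely bleeds
#'     one PSF width beyond the membrane; the margin keeps that zone and
#'     strips the far smoothing halo, so the extrasynaptic ROI tracks the
#'     membrane sheet with a bounded margin just as the synaptic anchor does
#'     through its z-window. Without it the two ROIs dilute their mean
#'     intensities by very different amounts and relative intensities are
#'     coverage-biased.}
#' }
#'
#' @param filtered numeric 3D array (typically the [meanFilter3D()] output).
#' @param thr a [ThresholdSpec-class]: \code{"otsu"} as described above, or a
#'   user value (applied directly, with the core at the same value).
#' @param anchor \code{"synaptic"} or \code{"extrasynaptic"}.
#' @param zRange optional integer \code{c(zlo, zhi)}: keep only these slices
#'   before extracting the largest component.
#' @param coreMargin halo margin around the membrane core kept in the
#'   extrasynaptic anchor, in voxels per axis (length 1 or 3; default 1;
#'   [analyzeStackCell()] passes the PSF FWHM in voxel units).
#' @return logical array (largest component above threshold); attributes
#'   \code{threshold} and \code{touchesBorder}.
#' @export
segmentRoi3D <- function(filtered, thr = thresholdSpec("otsu"),
                         anchor = c("synaptic", "extrasynaptic"),
                         zRange = NULL, coreMargin = 1L) {
  anchor <- match.arg(anchor)
  if (length(dim(filtered)) != 3L)
    scStop("segmentRoi3D expects a 3D array", "invalidParameter")
  if (any(!is.finite(filtered)))
    scStop("filtered stack must be finite", "invalidParameter")
  if (is.numeric(thr)) thr <- thresholdSpec(value = thr)
  if (identical(thr@method, "otsu")) {
    lv <- .otsu2(filtered)
    tval <- if (anchor == "synaptic") lv[2L] else lv[1L]
    core <- filtered > lv[2L]
  } else {
    tval <- .resolveThreshold(thr, filtered)
    core <- filtered > tval
  }
  above <- filtered > tval
  if (length(coreMargin) == 1L) coreMargin <- rep(coreMargin, 3L)
  if (anchor == "extrasynaptic" && any(coreMargin > 0L) && any(core))
    above <- above & .dilateBox(core, pmax(as.integer(coreMargin), 0L))
  if (!is.null(zRange)) {
    zr <- max(1L, zRange[1L]):min(dim(filtered)[3L], zRange[2L])
    keep <- array(FALSE, dim(filtered))
    keep[, , zr] <- TRUE
    above <- above & keep
  }
  if (!any(above))
    scStop("no voxels above the segmentation threshold", "emptySegmentation")
  mask <- .largestComponent(above)
  attr(mask, "threshold") <- tval
  attr(mask, "anchor") <- anchor
  attr(mask, "touchesBorder") <- .touchesBorder(mask)
  mask
}

#' Merge synaptic and extrasynaptic masks into an ROI set
#'
#' The synaptic mask is kept as-is; synaptic voxels are removed from the
#' extrasynaptic mask so the two regions are disjoint; the whole-cell
#' membrane is their exact union.
#'
#' @param greenMask logical array: synaptic anchor (from the green channel).
#' @param redMask logical array: extrasynaptic anchor (from the red channel).
#' @return a [RoiSet3D-class]
#' @export
buildRoiSet <- function(greenMask, redMask) {
  if (!identical(dim(greenMask), dim(redMask)))
    scStop("masks must have identical dimensions", "invalidParameter")
  if (!any(greenMask) && !any(redMask))
    scStop("both masks are empty", "invalidParameter")
  syn <- array(as.logical(greenMask), dim(greenMask))
  extra <- array(as.logical(redMask) & !syn, dim(redMask))
  new("RoiSet3D", synaptic = syn, extrasynaptic = extra,
      wholeCell = syn | extra)
}

#' Relative intensities per region and channel
#'
#' Mean intensity of the synaptic and extrasynaptic region per channel,
#' normalized by the whole-cell-membrane mean of the same channel
#' (RI > 1: accumulation; RI < 1: exclusion). Because the two regions
#' partition the whole-cell ROI, the voxel-weighted mean of the two relative
#' intensities is exactly 1 per channel; this identity is asserted.
#'
#' @param scene a [TwoChannelScene-class]: the stack to measure on (the
#'   pipeline measures on the original, unfiltered stack; smoothing is used
#'   for ROI generation only).
#' @param rois a [RoiSet3D-class] with both regions non-empty.
#' @return data.frame with columns \code{region}, \code{channel},
#'   \code{nVoxels}, \code{meanIntensity}, \code{relativeIntensity}; the
#'   whole-cell means are stored in attribute \code{wholeCellMeans}.
#' @export
relativeIntensities <- function(scene, rois) {
  stopifnot(is(scene, "TwoChannelScene"), is(rois, "RoiSet3D"))
  validObject(rois)
  if (!identical(dim(rois@synaptic), dim(scene@green)))
    scStop("ROI dimension does not match the scene", "invalidParameter")
  nSyn <- sum(rois@synaptic); nExt <- sum(rois@extrasynaptic)
  if (nSyn < 1L || nExt < 1L)
    scStop("synaptic and extrasynaptic regions must be non-empty",
           "invalidParameter")
  channels <- list(green = scene@green, red = scene@red)
  rows <- list()
  whole <- vapply(channels, function(ch) mean(ch[rois@wholeCell]), 0)
  for (chn in names(channels)) {
    ch <- channels[[chn]]
    for (reg in c("synaptic", "extrasynaptic")) {
      m <- mean(ch[slot(rois, reg)])
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, channel = chn,
        nVoxels = if (reg == "synaptic") nSyn else nExt,
        meanIntensity = m,
        relativeIntensity = m / whole[[chn]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  # exact identity for a disjoint-union ROI set
  for (chn in names(channels)) {
    sub <- out[out$channel == chn, ]
    wm <- sum(sub$nVoxels * sub$relativeIntensity) / sum(sub$nVoxels)
    if (abs(wm - 1) > 1e-9)
      scStop("relative-intensity identity violated (internal error)",
             "internalError")
  }
  attr(out, "wholeCellMeans") <- whole
  out
}

#' Histogram-intersection threshold
#'
#' Gating threshold defined as the crossing point of the intensity histograms
#' of cell-containing and cell-free (background) areas: both samples are
#' binned on a common grid, normalized to density, and the centre of the
#' first bin at or after the background mode where the cell density reaches
#' the background density is returned. (The search is not capped at the cell
#' mode: a cell ROI that contains many unlabeled voxels has its mode at the
#' background level, and the informative crossing sits just past it.) If the
#' densities never cross, the midpoint of the background and cell modes is
#' used. Identical distributions raise a no-threshold error.
#'
#' @param cellPixels,backgroundPixels numeric intensity samples.
#' @param nBins number of bins of the common grid (default 256).
#' @return numeric threshold
#' @examples
#' histogramIntersectionThreshold(rnorm(5000, 100, 10), rnorm(5000, 20, 10))
#' @export
histogramIntersectionThreshold <- function(cellPixels, backgroundPixels,
                                           nBins = 256L) {
  cellPixels <- cellPixels[is.finite(cellPixels)]
  backgroundPixels <- backgroundPixels[is.finite(backgroundPixels)]
  if (!length(cellPixels) || !length(backgroundPixels))
    scStop("both samples must be non-empty", "invalidParameter")
  rng <- range(c(cellPixels, backgroundPixels))
  if (rng[1] == rng[2])
    scStop("no intensity separation between cell and background",
           "noThreshold")
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  binOf <- function(v)
    tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                  nBins), nBins)
  hc <- binOf(cellPixels); hb <- binOf(backgroundPixels)
  dc <- hc / length(cellPixels); db <- hb / length(backgroundPixels)
  if (isTRUE(all.equal(dc, db)))
    scStop("cell and background distributions are indistinguishable",
           "noThreshold")
  iB <- which.max(db); iC <- which.max(dc)
  if (centers[iC] < centers[iB])
    scStop("cell mode below background mode", "invalidParameter")
  for (i in iB:nBins) {
    if (dc[i] >= db[i]) return(centers[i])
  }
  (centers[iB] + centers[iC]) / 2
}

#' Per-slice Pearson correlation with pixel gating
#'
#' For every z-slice, selects the ROI voxels that pass the either-channel
#' gate (above the gating threshold in at least one channel) and, when at
#' least \code{minPixels} qualify, computes the Pearson correlation for that
#' slice. The per-cell value is the unweighted mean over all computed slices;
#' slices below \code{minPixels} are skipped, never zero-filled. A 2D scene
#' is treated as a single slice (the unstimulated-control path).
#'
#' @param scene a [TwoChannelScene-class].
#' @param roi logical array restricting the analysis (synaptic or
#'   extrasynaptic ROI).
#' @param gateGreen,gateRed numeric gating thresholds (or
#'   [ThresholdSpec-class]; Otsu specs are resolved on the whole stack).
#' @param minPixels minimum gated pixels per slice (default 20).
#' @return list with \code{perSlice} (named numeric; \code{NA} for skipped
#'   slices), \code{cellMean}, \code{nSlicesUsed}, \code{nPixelsUsed}.
#' @export
perSlicePCC <- function(scene, roi, gateGreen = 0, gateRed = 0,
                        minPixels = 20L) {
  stopifnot(is(scene, "TwoChannelScene"))
  g <- scene@green; r <- scene@red
  if (!identical(dim(roi), dim(g)))
    scStop("ROI dimension does not match the scene", "invalidParameter")
  gG <- .resolveThreshold(gateGreen, g)
  gR <- .resolveThreshold(gateRed, r)
  nz <- if (length(dim(g)) == 3L) dim(g)[3L] else 1L
  perSlice <- rep(NA_real_, nz)
  names(perSlice) <- paste0("z", seq_len(nz))
  nUsed <- 0L
  for (z in seq_len(nz)) {
    if (length(dim(g)) == 3L) {
      gz <- g[, , z]; rz <- r[, , z]; mz <- roi[, , z]
    } else {
      gz <- g; rz <- r; mz <- roi
    }
    sel <- mz & (gz > gG | rz > gR)
    n <- sum(sel)
    if (n >= minPixels) {
      v <- .pcc(gz[sel], rz[sel])
      if (!is.na(v)) {
        perSlice[z] <- v
        nUsed <- nUsed + n
      }
    }
  }
  used <- which(!is.na(perSlice))
  if (!length(used))
    scStop("no slice reached the minimum gated pixel count",
           "insufficientData")
  list(perSlice = perSlice,
       cellMean = mean(perSlice[used]),
       nSlicesUsed = length(used),
       nPixelsUsed = nUsed)
}

#' Analyze one 3D stack cell
#'
#' The full stack pipeline: 3D mean filtering of both channels
#' ([meanFilter3D()]); ROI segmentation ([segmentRoi3D()]: synaptic anchor
#' from green, restricted to \code{contactZWindow} slices around the contact
#' plane located at the peak of the green per-slice intensity profile;
#' extrasynaptic anchor from red); ROI merging ([buildRoiSet()]);
#' relative intensities on the filtered channels ([relativeIntensities()]);
#' then, on the unfiltered scene, per-channel histogram-intersection gating
#' thresholds (background sample: voxels farther than one filter radius
#' outside the whole-cell ROI) and gated per-slice Pearson correlation
#' ([perSlicePCC()]) separately for the synaptic and extrasynaptic ROI.
#' Degenerate stages set QC flags rather than silently excluding the cell;
#' a failed segmentation raises an error (the cohort driver records it as a
#' failed cell).
#'
#' @param scene a 3D [TwoChannelScene-class].
#' @param filterRadius box filter radius per axis (default \code{c(3, 3, 3)},
#'   i.e. 7x7x7).
#' @param nBins histogram bins for the gating threshold (default 256).
#' @param minPixels minimum gated pixels per slice for the PCC (default 20).
#' @param thrGreen,thrRed segmentation threshold specs (default Otsu, see
#'   [segmentRoi3D()]).
#' @param contactZWindow z-window (slices below, slices above) around the
#'   contact plane for the synaptic anchor; the default \code{c(1, 2)} covers
#'   the axial PSF reach of the interface, extending one extra slice into the
#'   cell where the contact membrane actually lies. \code{NULL} disables the
#'   restriction.
#' @param resolutionLateral,resolutionAxial optical resolution (FWHM, nm)
#'   used to size the extrasynaptic halo margin (defaults 120 and 350); the
#'   margin is the FWHM rounded to voxel units.
#' @param gatePerSlice compute the gating threshold per slice instead of per
#'   stack (default \code{FALSE}: per stack).
#' @param cellId,condition labels for the output record.
#' @return a [CellMeasurement-class]
#' @export
analyzeStackCell <- function(scene, filterRadius = c(3L, 3L, 3L),
                             nBins = 256L, minPixels = 20L,
                             thrGreen = thresholdSpec("otsu"),
                             thrRed = thresholdSpec("otsu"),
                             contactZWindow = c(1L, 2L),
                             resolutionLateral = 120, resolutionAxial = 350,
                             gatePerSlice = FALSE,
                             cellId = NULL, condition = NULL) {
  stopifnot(is(scene, "TwoChannelScene"))
  if (length(dim(scene@green)) != 3L)
    scStop("analyzeStackCell expects a 3D scene", "invalidParameter")
  tr <- scene@truth
  cellId <- cellId %||% attr(scene, "cellId") %||% "cell"
  condition <- condition %||% (if (!is.null(tr)) tr@condition else "unknown")
  flags <- character()

  gf <- meanFilter3D(scene@green, filterRadius)
  rf <- meanFilter3D(scene@red, filterRadius)
  zRange <- NULL
  if (!is.null(contactZWindow)) {
    if (length(contactZWindow) == 1L)
      contactZWindow <- rep(contactZWindow, 2L)
    zStar <- which.max(apply(scene@green, 3L, sum))
    zRange <- c(zStar - contactZWindow[1L], zStar + contactZWindow[2L])
  }
  synMask <- segmentRoi3D(gf, thrGreen, "synaptic", zRange = zRange)
  margin <- pmax(1L, as.integer(round(
    c(resolutionLateral, resolutionLateral, resolutionAxial) /
      c(scene@pixelSizeLateral, scene@pixelSizeLateral, scene@zStep * 1000))))
  extraAnchor <- segmentRoi3D(rf, thrRed, "extrasynaptic",
                              coreMargin = margin)
  if (isTRUE(attr(synMask, "touchesBorder")))
    flags <- c(flags, "synaptic_touches_border")
  rois <- buildRoiSet(synMask, extraAnchor)
  validObject(rois)  # disjointness + union identity, asserted on every run

  riTab <- data.frame()
  if (sum(rois@extrasynaptic) >= 1L) {
    # intensities are quantified on the original stack; the mean-filtered
    # copies serve ROI generation only
    riTab <- relativeIntensities(scene, rois)
  } else {
    flags <- c(flags, "empty_extrasynaptic")
  }

  if (length(filterRadius) == 1L) filterRadius <- rep(filterRadius, 3L)
  bgMask <- !.dilateBox(rois@wholeCell, filterRadius)
  gateOne <- function(ch) {
    tryCatch(
      histogramIntersectionThreshold(ch[rois@wholeCell], ch[bgMask], nBins),
      SynapseColoc_error = function(e) NA_real_)
  }
  if (!any(bgMask)) {
    gG <- gR <- NA_real_
  } else {
    gG <- gateOne(scene@green)
    gR <- gateOne(scene@red)
  }
  if (is.na(gG) || is.na(gR)) {
    flags <- c(flags, "gate_fallback")
    if (is.na(gG)) gG <- 0
    if (is.na(gR)) gR <- 0
  }

  runPcc <- function(roi) {
    tryCatch(perSlicePCC(scene, roi, gG, gR, minPixels),
             SynapseColoc_error = function(e) NULL)
  }
  if (isTRUE(gatePerSlice)) {
    # optional per-slice gate: recompute the threshold within each slice
    runPcc <- function(roi) {
      nz <- dim(scene@green)[3L]
      perSlice <- rep(NA_real_, nz); names(perSlice) <- paste0("z", seq_len(nz))
      nUsed <- 0L
      for (z in seq_len(nz)) {
        gz <- scene@green[, , z]; rz <- scene@red[, , z]
        wz <- rois@wholeCell[, , z]; bz <- bgMask[, , z]
        if (!any(wz) || !any(bz)) next
        gGz <- tryCatch(histogramIntersectionThreshold(gz[wz], gz[bz], nBins),
                        SynapseColoc_error = function(e) 0)
        gRz <- tryCatch(histogramIntersectionThreshold(rz[wz], rz[bz], nBins),
                        SynapseColoc_error = function(e) 0)
        sel <- roi[, , z] & (gz > gGz | rz > gRz)
        if (sum(sel) >= minPixels) {
          v <- .pcc(gz[sel], rz[sel])
          if (!is.na(v)) { perSlice[z] <- v; nUsed <- nUsed + sum(sel) }
        }
      }
      used <- which(!is.na(perSlice))
      if (!length(used)) return(NULL)
      list(perSlice = perSlice, cellMean = mean(perSlice[used]),
           nSlicesUsed = length(used), nPixelsUsed = nUsed)
    }
  }
  pccSyn <- runPcc(rois@synaptic)
  pccExtra <- if (sum(rois@extrasynaptic) >= minPixels)
    runPcc(rois@extrasynaptic) else NULL
  if (is.null(pccSyn)) flags <- c(flags, "undefined_pcc")
  if (is.null(pccExtra)) flags <- c(flags, "undefined_pcc_extrasynaptic")

  new("CellMeasurement",
      cellId = cellId, condition = condition, modality = "stack3d",
      contactArea = NA_real_,
      pcc = if (!is.null(pccSyn)) pccSyn$cellMean else NA_real_,
      pccExtrasynaptic = if (!is.null(pccExtra)) pccExtra$cellMean else NA_real_,
      nPixelsUsed = as.integer(if (!is.null(pccSyn)) pccSyn$nPixelsUsed else 0L),
      nSlicesUsed = as.integer(if (!is.null(pccSyn)) pccSyn$nSlicesUsed else 0L),
      perSlicePcc = list(
        synaptic = if (!is.null(pccSyn)) pccSyn$perSlice else numeric(0),
        extrasynaptic = if (!is.null(pccExtra)) pccExtra$perSlice else numeric(0)),
      relativeIntensities = riTab,
      flags = unique(flags))
}

#' Analyze an unstimulated-control 2D slice
#'
#' Unengaged cells are too mobile for full stacks; they are measured on a
#' single 2D slice through the same gated per-slice correlation path. The
#' cell region is segmented on the mean-filtered slice (2-class Otsu on the
#' summed channels, largest component), the gate is the per-channel
#' histogram-intersection threshold against the area outside the dilated
#' cell region, and the slice PCC is reported.
#'
#' @param scene a 2D [TwoChannelScene-class].
#' @param filterRadius box radius for the 2D mean filter (default 3).
#' @param nBins,minPixels as in [analyzeStackCell()].
#' @param cellId,condition labels.
#' @return a [CellMeasurement-class]
#' @export
analyzeControlSlice <- function(scene, filterRadius = 3L, nBins = 256L,
                                minPixels = 20L, cellId = NULL,
                                condition = NULL) {
  stopifnot(is(scene, "TwoChannelScene"))
  if (length(dim(scene@green)) != 2L)
    scStop("analyzeControlSlice expects a 2D scene", "invalidParameter")
  tr <- scene@truth
  cellId <- cellId %||% attr(scene, "cellId") %||% "cell"
  condition <- condition %||% (if (!is.null(tr)) tr@condition else "unknown")
  k <- rep(1 / (2 * filterRadius + 1), 2L * filterRadius + 1L)
  sm <- .applyKernelAxis(.applyKernelAxis(scene@green + scene@red, k, 1L),
                         k, 2L)
  cellMask <- .largestComponent(sm > .otsu(sm))
  bgMask <- !.dilateBox(cellMask, c(filterRadius, filterRadius))
  gG <- tryCatch(histogramIntersectionThreshold(scene@green[cellMask],
                                                scene@green[bgMask], nBins),
                 SynapseColoc_error = function(e) 0)
  gR <- tryCatch(histogramIntersectionThreshold(scene@red[cellMask],
                                                scene@red[bgMask], nBins),
                 SynapseColoc_error = function(e) 0)
  res <- perSlicePCC(scene, cellMask, gG, gR, minPixels)
  new("CellMeasurement", cellId = cellId, condition = condition,
      modality = "tirf2d", contactArea = NA_real_, pcc = res$cellMean,
      nPixelsUsed = as.integer(res$nPixelsUsed), nSlicesUsed = 1L,
      flags = character())
}
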