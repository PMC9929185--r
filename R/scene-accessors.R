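#' Construct a two-channel scene from intensity arrays
#'
#' Wraps paired green/red intensity grids (e.g. read from real microscopy
#' exports) into a [TwoChannelScene-class]. Intensities must be finite and
#' non-negative.
#'
#' @param green,red numeric matrices (TIRF frames) or 3D arrays (stacks) of
#'   identical dimension.
#' @param pixelSizeLateral lateral pixel size in nm (default 160, the TIRF
#'   camera pixel; stacks conventionally use 100).
#' @param zStep axial step in micrometers (default 0.23).
#' @param modality \code{"tirf2d"} or \code{"stack3d"}; inferred from the
#'   array dimension when omitted.
#' @param truth optional [SceneTruth-class] for synthetic scenes.
#' @return a [TwoChannelScene-class]
#' @examples
#' sc <- twoChannelScene(matrix(1:4, 2), matrix(4:1, 2))
#' greenChannel(sc)
#' @export
twoChannelScene <- function(green, red, pixelSizeLateral = 160, zStep = 0.23,
                            modality = NULL, truth = NULL) {
  green <- as.array(green); red <- as.array(red)
  storage.mode(green) <- "double"; storage.mode(red) <- "double"
  if (is.null(modality))
    modality <- if (length(dim(green)) == 3L) "stack3d" else "tirf2d"
  new("TwoChannelScene", green = green, red = red,
      pixelSizeLateral = pixelSizeLateral, zStep = zStep,
      modality = modality, truth = truth)
}

#' @rdname TwoChannelScene-class
#' @export
setMethod("greenChannel", "TwoChannelScene", function(x) x@green)

#' @rdname TwoChannelScene-class
#' @export
setMethod("redChannel", "TwoChannelScene", function(x) x@red)

#' @rdname TwoChannelScene-class
#' @export
setMethod("sceneTruthOf", "TwoChannelScene", function(x) x@truth)

#' @rdname TwoChannelScene-class
#' @export
setMethod("modalityOf", "TwoChannelScene", function(x) x@modality)

#' @rdname TwoChannelScene-class
#' @export
setMethod("pixelSize", "TwoChannelScene", function(x) x@pixelSizeLateral)

#' @rdname TwoChannelScene-class
#' @export
setMethod("zStep", "TwoChannelScene", function(x) x@zStep)

#' @rdname TwoChannelScene-class
#' @export
setMethod("sceneDepth", "TwoChannelScene", function(x) {
  d <- dim(x@green)
  if (length(d) == 3L) d[3L] * x@zStep else NA_real_
})

setMethod("show", "TwoChannelScene", function(object) {
  d <- dim(object@green)
  cat("TwoChannelScene (", object@modality, ")\n", sep = "")
  cat("  grid: ", paste(d, collapse = " x "),
      "  pixel ", object@pixelSizeLateral, " nm", sep = "")
  if (length(d) == 3L)
    cat(", z-step ", object@zStep, " um (depth ",
        format(sceneDepth(object), digits = 3), " um)", sep = "")
  cat("\n  intensity range: green [",
      paste(format(range(object@green), digits = 4), collapse = ", "),
      "], red [",
      paste(format(range(object@red), digits = 4), collapse = ", "), "]\n",
      sep = "")
  if (!is.null(object@truth))
    cat("  truth: condition '", object@truth@condition,
        "', coloc fraction ", object@truth@colocFraction,
        ", seed ", object@truth@seed, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth (", object@modality, ", condition '", object@condition,
      "')\n", sep = "")
  cat("  grid ", paste(object@gridDim, collapse = " x "),
      ", pixel ", object@pixelSizeLateral, " nm, z-step ", object@zStep,
      " um\n", sep = "")
  cat("  cell radius ", object@cellRadius, " um, cap angle ",
      format(object@capAngle, digits = 3), " rad\n", sep = "")
  cat("  enrichment green/red ", object@enrichmentGreen, "/",
      object@enrichmentRed, ", coloc fraction ", object@colocFraction,
      "\n", sep = "")
  cat("  density ", object@baselineDensity, "/um^2, ",
      object@photonsPerReceptor, " photons/molecule, background ",
      object@background, ", read noise ", object@readNoiseSd,
      ", shot noise ", object@shotNoise, "\n", sep = "")
  cat("  seed ", object@seed, "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "RoiSet3D", function(object) {
  cat("RoiSet3D: synaptic ", sum(object@synaptic),
      " | extrasynaptic ", sum(object@extrasynaptic),
      " | whole cell ", sum(object@wholeCell), " voxels\n", sep = "")
  invisible(NULL)
})

setMethod("show", "CellMeasurement", function(object) {
  cat("CellMeasurement '", object@cellId, "' (", object@condition, ", ",
      object@modality, ")\n", sep = "")
  if (!is.na(object@contactArea))
    cat("  contact area: ", format(object@contactArea, digits = 4),
        " um^2\n", sep = "")
  cat("  pcc: ", format(object@pcc, digits = 4), sep = "")
  if (!is.na(object@pccExtrasynaptic))
    cat("  (extrasynaptic: ", format(object@pccExtrasynaptic, digits = 4),
        ")", sep = "")
  cat("  [n = ", object@nPixelsUsed, " px", sep = "")
  if (!is.na(object@nSlicesUsed))
    cat(", ", object@nSlicesUsed, " slices", sep = "")
  cat("]\n")
  if (length(object@flags))
    cat("  flags: ", paste(object@flags, collapse = ", "), "\n", sep = "")
  invisible(NULL)
})

#' Flatten per-cell measurements to a data.frame
#'
#' One row per cell with the scalar fields of [CellMeasurement-class];
#' relative intensities are spread into columns named
#' \code{ri_<region>_<channel>}.
#'
#' @param x a \code{CellMeasurement} or a list of them.
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return a data.frame
#' @export
as.data.frame.CellMeasurement <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  df <- data.frame(
    cell_id = x@cellId, condition = x@condition, modality = x@modality,
    contact_area_um2 = x@contactArea, pcc = x@pcc,
    pcc_extrasynaptic = x@pccExtrasynaptic,
    n_pixels_used = x@nPixelsUsed, n_slices_used = x@nSlicesUsed,
    flags = paste(x@flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
  ri <- x@relativeIntensities
  if (nrow(ri)) {
    for (i in seq_len(nrow(ri))) {
      df[[paste0("ri_", ri$region[i], "_", ri$channel[i])]] <-
        ri$relativeIntensity[i]
      df[[paste0("nvox_", ri$region[i])]] <- ri$nVoxels[i]
    }
  }
  df
}

#' @describeIn as.data.frame.CellMeasurement list method: row-binds the
#'   per-cell data.frames, filling missing columns with \code{NA}.
#' @export
measurementsToDataFrame <- function(x) {
  if (is(x, "CellMeasurement")) x <- list(x)
  rows <- lapply(x, as.data.frame.CellMeasurement)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(cols, names(r))) r[[cc]] <- NA
    r[cols]
  })
  do.call(rbind, rows)
}
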