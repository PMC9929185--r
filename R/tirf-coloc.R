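#' Threshold specification constructor
#'
#' @param method \code{"otsu"} (default: Otsu's threshold computed on the
#'   data being gated), \code{"user"} (explicit \code{value}), or
#'   \code{"histogram_intersect"} (crossing of cell/background intensity
#'   histograms; only valid where background samples are available, see
#'   [histogramIntersectionThreshold()]).
#' @param value numeric threshold for \code{method = "user"}; supplying a
#'   value implies \code{method = "user"}.
#' @return a [ThresholdSpec-class]
#' @examples
#' thresholdSpec()            # Otsu
#' thresholdSpec(value = 50)  # fixed user threshold
#' @export
thresholdSpec <- function(method = c("otsu", "user", "histogram_intersect"),
                          value = NA_real_) {
  if (!missing(value) && !is.na(value) && missing(method)) method <- "user"
  method <- match.arg(method)
  new("ThresholdSpec", method = method, value = as.numeric(value))
}

# Resolve a ThresholdSpec against the values it gates.
.resolveThreshold <- function(spec, values) {
  if (is.numeric(spec)) return(spec)  # convenience: plain numbers pass through
  stopifnot(is(spec, "ThresholdSpec"))
  switch(spec@method,
    user = spec@value,
    otsu = .otsu(values),
    histogram_intersect = scStop(
      "histogram_intersect needs explicit cell/background samples; compute the value with histogramIntersectionThreshold() and pass it as a user threshold",
      "invalidParameter")
  )
}

#' Select contact-region pixels by per-channel gating
#'
#' Marks pixels whose intensity exceeds the threshold in at least one of the
#' two channels (the OR rule used to define the TIRF contact ROI: a pixel
#' belongs to the contact if either the reference receptor or the probe is
#' above threshold there).
#'
#' @param scene a 2D [TwoChannelScene-class].
#' @param thrGreen,thrRed per-channel [ThresholdSpec-class] (or plain
#'   numeric thresholds); default Otsu per channel.
#' @return logical matrix; attributes \code{thresholdGreen} /
#'   \code{thresholdRed} record the resolved values.
#' @examples
#' sc <- twoChannelScene(matrix(c(0, 10, 0, 10), 2), matrix(c(0, 0, 10, 0), 2))
#' selectRoiPixels(sc, thresholdSpec(value = 5), thresholdSpec(value = 5))
#' @export
selectRoiPixels <- function(scene, thrGreen = thresholdSpec("otsu"),
                            thrRed = thresholdSpec("otsu")) {
  stopifnot(is(scene, "TwoChannelScene"))
  if (length(dim(scene@green)) != 2L)
    scStop("selectRoiPixels expects a 2D scene", "invalidParameter")
  tg <- .resolveThreshold(thrGreen, scene@green)
  tr <- .resolveThreshold(thrRed, scene@red)
  mask <- scene@green > tg | scene@red > tr
  attr(mask, "thresholdGreen") <- tg
  attr(mask, "thresholdRed") <- tr
  mask
}

#' Contact area from a pixel mask
#'
#' Number of selected pixels multiplied by the pixel area (default
#' 160 x 160 nm^2), in um^2.
#'
#' @param mask logical 2D mask.
#' @param pixelSizeLateral pixel size in nm.
#' @return area in um^2
#' @examples
#' contactArea(matrix(TRUE, 1, 1))        # 0.0256 um^2 at 160 nm pixels
#' @export
contactArea <- function(mask, pixelSizeLateral = 160) {
  if (length(dim(mask)) != 2L)
    scStop("contactArea expects a 2D mask", "invalidParameter")
  sum(mask) * (pixelSizeLateral / 1000)^2
}

# Core correlation on paired vectors; NA_real_ flags an undefined
# correlation (zero variance), deliberately distinct from r = 0.
.pcc <- function(x, y) {
  if (max(x) == min(x) || max(y) == min(y)) return(NA_real_)
  stats::cor(x, y)
}

#' Pearson correlation over masked pixels
#'
#' r = sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2)
#' sum((y - mean(y))^2)) over the pixels selected by \code{mask}, where x and
#' y are the green and red intensities per pixel. A channel with zero
#' variance on the mask yields \code{NA} (undefined correlation, not zero);
#' fewer than two selected pixels is an error.
#'
#' @param scene a [TwoChannelScene-class] (2D or 3D).
#' @param mask logical mask of the same dimension.
#' @return correlation in [-1, 1], or \code{NA} if undefined
#' @examples
#' sc <- twoChannelScene(matrix(1:4, 2), matrix(c(2, 1, 4, 3), 2))
#' pearsonCC(sc, matrix(TRUE, 2, 2))  # 0.6
#' @export
pearsonCC <- function(scene, mask) {
  stopifnot(is(scene, "TwoChannelScene"))
  if (!identical(dim(mask), dim(scene@green)))
    scStop("mask dimension does not match the scene", "invalidParameter")
  x <- scene@green[mask]
  y <- scene@red[mask]
  if (length(x) < 2L)
    scStop("fewer than 2 pixels selected for correlation", "insufficientData")
  .pcc(x, y)
}

#' Analyze one TIRF cell
#'
#' Composes the 2D analysis: gated pixel selection ([selectRoiPixels()]),
#' contact size ([contactArea()]) and Pearson correlation ([pearsonCC()])
#' over the gated ROI. An empty ROI yields contact area 0 and an undefined
#' (NA) correlation with an explanatory flag.
#'
#' @param scene a 2D [TwoChannelScene-class].
#' @param thrGreen,thrRed per-channel [ThresholdSpec-class].
#' @param cellId,condition labels for the output record; defaults are taken
#'   from the embedded truth when present.
#' @return a [CellMeasurement-class]
#' @export
analyzeTirfCell <- function(scene, thrGreen = thresholdSpec("otsu"),
                            thrRed = thresholdSpec("otsu"),
                            cellId = NULL, condition = NULL) {
  stopifnot(is(scene, "TwoChannelScene"))
  tr <- scene@truth
  cellId <- cellId %||% attr(scene, "cellId") %||% "cell"
  condition <- condition %||% (if (!is.null(tr)) tr@condition else "unknown")
  mask <- selectRoiPixels(scene, thrGreen, thrRed)
  n <- sum(mask)
  area <- contactArea(mask, scene@pixelSizeLateral)
  flags <- character()
  if (n < 2L) {
    pcc <- NA_real_
    flags <- c(flags, "empty_roi", "undefined_pcc")
  } else {
    pcc <- pearsonCC(scene, mask)
    if (is.na(pcc)) flags <- c(flags, "undefined_pcc")
  }
  new("CellMeasurement", cellId = cellId, condition = condition,
      modality = "tirf2d", contactArea = area, pcc = pcc,
      nPixelsUsed = as.integer(n), flags = flags)
}
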