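# Scene I/O: 2-channel multi-page TIFF + plain-text key-value sidecars.

.sidecarPath <- function(path) paste0(path, ".meta.txt")
.truthPath <- function(path) paste0(path, ".truth.txt")

.writeKeyValue <- function(x, path) {
  writeLines(paste0(names(x), "=", vapply(x, function(v)
    paste(format(v, digits = 17, scientific = FALSE), collapse = ","),
    "")), path)
}

.readKeyValue <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)
  out <- lapply(kv, `[`, 2L)
  names(out) <- vapply(kv, `[`, "", 1L)
  out
}

.truthToList <- function(truth) {
  sl <- slotNames("SceneTruth")
  stats::setNames(lapply(sl, function(s) slot(truth, s)), sl)
}

.truthFromList <- function(kv) {
  num <- function(k) as.numeric(strsplit(kv[[k]], ",")[[1L]])
  new("SceneTruth",
      modality = kv$modality,
      gridDim = as.integer(num("gridDim")),
      pixelSizeLateral = num("pixelSizeLateral"), zStep = num("zStep"),
      cellRadius = num("cellRadius"), capAngle = num("capAngle"),
      enrichmentGreen = num("enrichmentGreen"),
      enrichmentRed = num("enrichmentRed"),
      colocFraction = num("colocFraction"),
      baselineDensity = num("baselineDensity"),
      photonsPerReceptor = num("photonsPerReceptor"),
      background = num("background"), readNoiseSd = num("readNoiseSd"),
      psfSigmaLateral = num("psfSigmaLateral"),
      psfSigmaAxial = num("psfSigmaAxial"),
      tirfContrast = num("tirfContrast"),
      shotNoise = identical(kv$shotNoise, "TRUE"),
      seed = as.integer(num("seed")),
      condition = kv$condition)
}

#' Write a scene as a two-channel multi-page TIFF
#'
#' Pages are channel-major (all green z-pages, then all red), 16-bit
#' unsigned; intensities are clamped to [0, 65535] and rounded (the
#' generators already emit integer counts, so synthetic scenes round-trip
#' bit-identically). Calibration goes to a plain-text key-value sidecar
#' \code{<path>.meta.txt} (keys \code{pixel_size_nm}, \code{z_step_um},
#' \code{modality}, \code{condition}, \code{n_z}); an embedded
#' [SceneTruth-class] is serialized to \code{<path>.truth.txt}.
#'
#' @param scene a [TwoChannelScene-class].
#' @param path output TIFF path.
#' @return \code{path}, invisibly
#' @export
writeScene <- function(scene, path) {
  stopifnot(is(scene, "TwoChannelScene"))
  toPages <- function(a) {
    a <- pmin(pmax(round(a), 0), 65535) / 65535
    if (length(dim(a)) == 2L) list(a)
    else lapply(seq_len(dim(a)[3L]), function(z) a[, , z])
  }
  pages <- c(toPages(scene@green), toPages(scene@red))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  nz <- if (length(dim(scene@green)) == 3L) dim(scene@green)[3L] else 1L
  .writeKeyValue(list(
    pixel_size_nm = scene@pixelSizeLateral,
    z_step_um = scene@zStep,
    modality = scene@modality,
    condition = if (!is.null(scene@truth)) scene@truth@condition else "unknown",
    n_z = nz), .sidecarPath(path))
  if (!is.null(scene@truth))
    .writeKeyValue(.truthToList(scene@truth), .truthPath(path))
  invisible(path)
}

#' Read a two-channel scene from a multi-page TIFF
#'
#' Inverse of [writeScene()]: expects channel-major page order (green pages
#' first). A missing sidecar triggers defaults (160 nm pixels, 0.23 um
#' z-step, modality from the page count) with a warning. Page counts that
#' cannot split into two equal channels are a format error.
#'
#' @param path TIFF path written by [writeScene()] (or equally formatted
#'   data).
#' @return a [TwoChannelScene-class] (with truth attached when a truth
#'   sidecar is present)
#' @export
readScene <- function(path) {
  if (!file.exists(path))
    scStop(sprintf("no such file: %s", path), "formatError")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # tolerate grey-stored-as-RGB
    round(p * 65535)
  })
  meta <- NULL
  if (file.exists(.sidecarPath(path))) {
    meta <- .readKeyValue(.sidecarPath(path))
  } else {
    scWarn(sprintf("missing sidecar for %s; assuming defaults", path),
           "missingSidecar")
  }
  px <- if (!is.null(meta$pixel_size_nm)) as.numeric(meta$pixel_size_nm) else 160
  zs <- if (!is.null(meta$z_step_um)) as.numeric(meta$z_step_um) else 0.23
  n <- length(pages)
  if (n %% 2L != 0L)
    scStop(sprintf("page count %d does not split into 2 channels", n),
           "formatError")
  nz <- n %/% 2L
  modality <- if (!is.null(meta$modality)) meta$modality
              else if (nz == 1L) "tirf2d" else "stack3d"
  if (modality == "tirf2d" && nz != 1L)
    scStop(sprintf("tirf2d scene must have exactly 2 pages, found %d", n),
           "formatError")
  if (!is.null(meta$n_z) && as.integer(meta$n_z) != nz)
    scStop(sprintf("sidecar declares %s z-pages per channel, file has %d",
                   meta$n_z, nz), "formatError")
  stackUp <- function(ps) {
    if (length(ps) == 1L) ps[[1L]]
    else array(unlist(ps), c(dim(ps[[1L]]), length(ps)))
  }
  g <- stackUp(pages[seq_len(nz)])
  r <- stackUp(pages[nz + seq_len(nz)])
  truth <- if (file.exists(.truthPath(path)))
    .truthFromList(.readKeyValue(.truthPath(path))) else NULL
  twoChannelScene(g, r, pixelSizeLateral = px, zStep = zs,
                  modality = modality, truth = truth)
}
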