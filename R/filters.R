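# Separable array filtering, Otsu thresholding and 3D connected components.

# Reflect ("symmetric", edge-inclusive) padding indices for one axis.
.padIdx <- function(n, r) {
  if (r > n) scStop("kernel radius exceeds axis extent", "invalidParameter")
  c(rev(seq_len(r)), seq_len(n), seq(n, by = -1L, length.out = r))
}

# Apply a 1D kernel along one axis of a 2D/3D array with reflect padding.
.applyKernelAxis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(a * k)
  pid <- .padIdx(n, r)
  out <- array(0, d)
  if (length(d) == 2L) {
    ap <- if (axis == 1L) a[pid, , drop = FALSE] else a[, pid, drop = FALSE]
    for (j in seq_along(k)) {
      out <- out + k[j] * (if (axis == 1L) ap[j:(j + n - 1L), , drop = FALSE]
                           else ap[, j:(j + n - 1L), drop = FALSE])
    }
  } else {
    ap <- switch(axis, a[pid, , , drop = FALSE], a[, pid, , drop = FALSE],
                 a[, , pid, drop = FALSE])
    for (j in seq_along(k)) {
      sl <- switch(axis,
        ap[j:(j + n - 1L), , , drop = FALSE],
        ap[, j:(j + n - 1L), , drop = FALSE],
        ap[, , j:(j + n - 1L), drop = FALSE])
      out <- out + k[j] * sl
    }
  }
  out
}

.gaussKernel <- function(sigma) {
  if (sigma < 1e-8) return(1)
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(-r:r)^2 / (2 * sigma^2))
  w / sum(w)
}

# Separable Gaussian blur; sigmas in voxel units, one per axis.
.gaussianBlur <- function(a, sigmas) {
  for (ax in seq_along(dim(a))) {
    k <- .gaussKernel(sigmas[ax])
    if (length(k) > 1L) {
      # clip kernel to the axis extent for very small arrays
      r <- (length(k) - 1L) %/% 2L
      n <- dim(a)[ax]
      if (r > n) {
        k <- k[(r - n + 1L):(length(k) - (r - n))]
        k <- k / sum(k)
      }
      a <- .applyKernelAxis(a, k, ax)
    }
  }
  a
}

#' 3D box mean filter
#'
#' Separable box average over a \code{(2r+1)} window per axis (the default
#' radius 3 per axis gives the 7x7x7 neighbourhood used to smooth confocal
#' stacks before segmentation), with reflect (symmetric, edge-inclusive)
#' padding at the borders.
#'
#' @param stack numeric 3D array.
#' @param radius integer radius per axis (length 1 or 3), each >= 1 and at
#'   most the corresponding axis extent.
#' @return filtered array of the same dimension
#' @examples
#' a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
#' f <- meanFilter3D(a)
#' f[5, 5, 5] * 343  # the impulse spreads to 1/343 over the 7^3 box
#' @export
meanFilter3D <- function(stack, radius = c(3L, 3L, 3L)) {
  if (length(dim(stack)) != 3L)
    scStop("meanFilter3D expects a 3D array", "invalidParameter")
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  radius <- as.integer(radius)
  if (length(radius) != 3L || any(is.na(radius)) || any(radius < 1L))
    scStop("radius must be >= 1 per axis", "invalidParameter")
  if (any(radius > dim(stack)))
    scStop("filter radius larger than axis extent", "invalidParameter")
  for (ax in 1:3) {
    k <- rep(1 / (2 * radius[ax] + 1), 2L * radius[ax] + 1L)
    stack <- .applyKernelAxis(stack, k, ax)
  }
  stack
}

# Pooled-histogram Otsu threshold (single split). Returns the bin edge
# separating the two classes; values strictly above it form the upper class.
.otsu <- function(x, nBins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nBins)
  h <- tabulate(bin, nBins)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * centers)
  wt <- w[nBins]; mt <- m[nBins]
  w0 <- w[-nBins]; m0 <- m[-nBins]
  w1 <- wt - w0
  valid <- w0 > 0 & w1 > 0
  val <- rep(-Inf, nBins - 1L)
  val[valid] <- (m0[valid] / w0[valid] - (mt - m0[valid]) / w1[valid])^2 *
    w0[valid] * w1[valid]
  edges[which.max(val) + 1L]
}

# Two-level (3-class) Otsu: returns c(lower, upper) bin-edge thresholds that
# jointly maximize between-class variance. Used to separate background,
# membrane and the bright synaptic accumulation in one deterministic step.
.otsu2 <- function(x, nBins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2]) return(c(rng[1], rng[1]))
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), nBins)
  h <- tabulate(bin, nBins)
  centers <- (edges[-1L] + edges[-(nBins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * centers)
  wt <- w[nBins]; mt <- m[nBins]
  # thresholds after bins a < b
  a <- seq_len(nBins - 2L)
  b <- seq_len(nBins - 1L)
  W0 <- matrix(w[a], length(a), length(b))
  M0 <- matrix(m[a], length(a), length(b))
  Wb <- matrix(w[b], length(a), length(b), byrow = TRUE)
  Mb <- matrix(m[b], length(a), length(b), byrow = TRUE)
  W1 <- Wb - W0; M1 <- Mb - M0
  W2 <- wt - Wb; M2 <- mt - Mb
  ok <- outer(a, b, "<") & W0 > 0 & W1 > 0 & W2 > 0
  val <- matrix(-Inf, length(a), length(b))
  val[ok] <- M0[ok]^2 / W0[ok] + M1[ok]^2 / W1[ok] + M2[ok]^2 / W2[ok]
  best <- arrayInd(which.max(val), dim(val))
  c(edges[a[best[1L]] + 1L], edges[b[best[2L]] + 1L])
}

# Largest 26-connected component of a 3D logical mask (ties broken by the
# component containing the smallest linear index). 2D masks use the analogous
# 8-neighbourhood.
.largestComponent <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(mask)
  nd <- length(d)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  co <- arrayInd(idx, d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # half the offsets suffice for an undirected edge list
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0)[1L]
    o[nz] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  strides <- cumprod(c(1L, d[-nd]))
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    valid <- rep(TRUE, length(idx))
    for (ax in seq_len(nd)) {
      cn <- co[, ax] + o[ax]
      valid <- valid & cn >= 1L & cn <= d[ax]
    }
    nlin <- idx + as.integer(sum(o * strides))
    inMask <- valid
    inMask[valid] <- pos[nlin[valid]] > 0L
    from <- c(from, pos[idx[inMask]])
    to <- c(to, pos[nlin[inMask]])
  }
  if (length(from)) {
    g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    comp <- igraph::components(g)
    largest <- which.max(comp$csize)  # first max: deterministic tie-break
    sel <- idx[comp$membership[seq_along(idx)] == largest]
  } else {
    sel <- idx[1L]
  }
  out <- array(FALSE, d)
  out[sel] <- TRUE
  out
}

# Binary dilation by a box of the given radii (via the separable box filter).
.dilateBox <- function(mask, radius) {
  a <- array(as.double(mask), dim(mask))
  for (ax in seq_along(dim(mask))) {
    r <- radius[min(ax, length(radius))]
    k <- rep(1, 2L * r + 1L)
    a <- .applyKernelAxis(a, k, ax)
  }
  a > 1e-9
}

.touchesBorder <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  for (ax in seq_len(nd)) {
    idx <- lapply(seq_len(nd), function(i) seq_len(d[i]))
    for (edge in c(1L, d[ax])) {
      idx[[ax]] <- edge
      if (any(do.call(`[`, c(list(mask), idx)))) return(TRUE)
    }
  }
  FALSE
}
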