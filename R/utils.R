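## Internal numeric helpers shared across modules.

#' @importFrom stats setNames
NULL

## Deterministic 32-bit seed derived from a base seed and string tags.
## Polynomial string hash mod (2^31 - 1); products stay < 2^53 so doubles
## carry them exactly.
.deriveSeed <- function(base, ...) {
  s <- paste(c(format(base), ...), collapse = "/")
  h <- as.double(base) %% 2147483647
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

## Evaluate expr under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Shift a 3-D array by an integer voxel offset; vacated positions become NA.
## out[i] == a[i + off] where defined.
.shiftArr <- function(a, off) {
  d <- dim(a)
  out <- array(a[NA_integer_][1L], dim = d)  # NA of matching type
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      dstr <- seq_len(max(0L, d[ax] - o)); srcr <- dstr + o
    } else {
      srcr <- seq_len(max(0L, d[ax] + o)); dstr <- srcr - o
    }
    if (length(srcr) == 0L) return(out)
    src[[ax]] <- srcr; dst[[ax]] <- dstr
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

.gaussKernel1d <- function(sigma_mm, spacing) {
  if (sigma_mm <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_mm / spacing))
  x <- (-r:r) * spacing
  k <- exp(-x^2 / (2 * sigma_mm^2))
  k / sum(k)
}

## Separable convolution along one axis via a dense banded matrix;
## edge rows are renormalised so constants are preserved exactly.
.convolveAxis <- function(arr, k, axis) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1L & j <= n
    K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[o + r + 1L]
  }
  K <- K / rowSums(K)
  out <- array(K %*% m, dim = d[perm])
  aperm(out, order(perm))
}

## Isotropic-in-mm Gaussian smoothing of a 3-D array (FWHM in mm).
.gaussSmooth <- function(arr, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3)
    arr <- .convolveAxis(arr, .gaussKernel1d(sigma, spacing[ax]), ax)
  arr
}

## World coordinates (mm) of voxel centres along each axis.
.axisCoords <- function(d, spacing, origin) {
  lapply(1:3, function(ax) origin[ax] + (seq_len(d[ax]) - 1) * spacing[ax])
}

## Logical mask of an axis-aligned ellipsoid. Plain voxel-centre inclusion
## misstates the volume by up to ~20% on a 4 mm grid, so the digitisation is
## volume-preserving: interior voxels are taken outright and boundary-band
## voxels are ranked by fractional coverage (sub-voxel sampling) until the
## voxel count matches the analytic ellipsoid volume to within half a voxel.
.ellipsoidMask <- function(d, spacing, origin, centre, radii,
                           volumePreserving = TRUE) {
  co <- .axisCoords(d, spacing, origin)
  q1 <- ((co[[1L]] - centre[1L]) / radii[1L])^2
  q2 <- ((co[[2L]] - centre[2L]) / radii[2L])^2
  q3 <- ((co[[3L]] - centre[3L]) / radii[3L])^2
  q <- outer(outer(q1, q2, `+`), q3, `+`)
  if (!volumePreserving) return(q <= 1)
  hs <- 1.2 * sqrt(sum((spacing / 2)^2)) / min(radii)  # band half-width
  inner <- q <= max(0, 1 - hs)^2
  bandIdx <- which(q > max(0, 1 - hs)^2 & q <= (1 + hs)^2)
  k <- max(1L, round(4 / 3 * pi * prod(radii) / prod(spacing)))
  if (length(bandIdx) == 0L) return(inner)
  ns <- 4L
  sub <- (seq_len(ns) - 0.5) / ns - 0.5
  pts <- arrayInd(bandIdx, d)
  frac <- numeric(length(bandIdx))
  for (ox in sub) for (oy in sub) for (oz in sub) {
    x <- (origin[1L] + (pts[, 1L] - 1 + ox) * spacing[1L] - centre[1L]) /
      radii[1L]
    y <- (origin[2L] + (pts[, 2L] - 1 + oy) * spacing[2L] - centre[2L]) /
      radii[2L]
    z <- (origin[3L] + (pts[, 3L] - 1 + oz) * spacing[3L] - centre[3L]) /
      radii[3L]
    frac <- frac + (x^2 + y^2 + z^2 <= 1)
  }
  frac <- frac / ns^3
  mask <- inner
  extra <- k - sum(inner)
  if (extra > 0L) {
    ord <- order(-frac, q[bandIdx])
    take <- ord[seq_len(min(extra, sum(frac > 0)))]
    mask[bandIdx[take]] <- TRUE
  }
  mask
}

## Trilinear interpolation of arr (grid: spacing/origin at voxel centres) at
## world points given as three coordinate vectors of an output grid.
## Coordinates are clamped to the voxel-centre hull (edge replication).
.trilinearGrid <- function(arr, spacing, origin, xs, ys, zs) {
  d <- dim(arr)
  fi <- function(v, ax) pmin(pmax((v - origin[ax]) / spacing[ax] + 1, 1), d[ax])
  gx <- fi(xs, 1L); gy <- fi(ys, 2L); gz <- fi(zs, 3L)
  x0 <- pmin(floor(gx), d[1L] - 1L); x0[d[1L] == 1L] <- 1L
  y0 <- pmin(floor(gy), d[2L] - 1L); y0[d[2L] == 1L] <- 1L
  z0 <- pmin(floor(gz), d[3L] - 1L); z0[d[3L] == 1L] <- 1L
  fx <- gx - x0; fy <- gy - y0; fz <- gz - z0
  if (d[1L] == 1L) fx[] <- 0
  if (d[2L] == 1L) fy[] <- 0
  if (d[3L] == 1L) fz[] <- 0
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X0 <- rep(x0, times = ny * nz); FX <- rep(fx, times = ny * nz)
  Y0 <- rep(rep(y0, each = nx), times = nz); FY <- rep(rep(fy, each = nx), times = nz)
  Z0 <- rep(z0, each = nx * ny); FZ <- rep(fz, each = nx * ny)
  lin <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  x1 <- pmin(X0 + 1L, d[1L]); y1 <- pmin(Y0 + 1L, d[2L]); z1 <- pmin(Z0 + 1L, d[3L])
  v <- lin(X0, Y0, Z0) * (1 - FX) * (1 - FY) * (1 - FZ) +
    lin(x1, Y0, Z0) * FX * (1 - FY) * (1 - FZ) +
    lin(X0, y1, Z0) * (1 - FX) * FY * (1 - FZ) +
    lin(x1, y1, Z0) * FX * FY * (1 - FZ) +
    lin(X0, Y0, z1) * (1 - FX) * (1 - FY) * FZ +
    lin(x1, Y0, z1) * FX * (1 - FY) * FZ +
    lin(X0, y1, z1) * (1 - FX) * FY * FZ +
    lin(x1, y1, z1) * FX * FY * FZ
  array(v, dim = c(nx, ny, nz))
}

## Bounding box (index ranges) of TRUE voxels, expanded by a voxel margin.
.maskBBox <- function(mask, margin = 0L) {
  d <- dim(mask)
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2L, min) - margin, 1L)
  hi <- pmin(apply(w, 2L, max) + margin, d)
  list(lo = lo, hi = hi)
}
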