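## Intensity-based feature families: local intensity peaks, intensity
## statistics, intensity histogram, intensity-volume histogram. Population
## (1/N) moment conventions throughout; degenerate quantities (skewness of a
## constant region, CoV at zero mean, ...) return NaN rather than a
## substituted zero, so they can be excluded downstream.

.popMoments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  list(n = n, mu = mu, var = v, sd = sqrt(v))
}

.skewKurt <- function(x, mo) {
  if (mo$var == 0) return(c(NaN, NaN))
  m3 <- mean((x - mo$mu)^3)
  m4 <- mean((x - mo$mu)^4)
  c(m3 / mo$sd^3, m4 / mo$var^2 - 3)
}

#' Local and global intensity peaks
#'
#' The local intensity peak is the mean SUV inside a 1 cm^3 sphere (radius
#' 6.204 mm) centred on the hottest VOI voxel (among tied maxima the highest
#' sphere mean is taken); the global peak is the largest sphere mean over
#' all VOI voxels. Sphere means include voxels outside the VOI but inside
#' the image, normalised by the in-image sphere voxel count.
#'
#' @param scan_suv a \linkS4class{ScanVolume} in SUV units.
#' @param voi a \linkS4class{VoiMask}.
#' @return named numeric(2): \code{loc.peak_local}, \code{loc.peak_global}.
#' @export
computeLocalIntensity <- function(scan_suv, voi) {
  a <- voxelValues(scan_suv)
  m <- maskArray(voi)
  sp <- voxelSpacing(scan_suv)
  r <- (3 / (4 * pi) * 1000)^(1 / 3)  # radius of a 1 cm^3 sphere in mm
  rg <- lapply(1:3, function(ax) -floor(r / sp[ax]):floor(r / sp[ax]))
  offs <- as.matrix(expand.grid(rg[[1]], rg[[2]], rg[[3]]))
  offs <- offs[sqrt(colSums((t(offs) * sp)^2)) <= r + 1e-9, , drop = FALSE]
  sumA <- array(0, dim(a)); cnt <- array(0L, dim(a))
  one <- array(1, dim(a))
  for (i in seq_len(nrow(offs))) {
    sh <- .shiftArr(a, offs[i, ])
    w <- !is.na(sh)
    sumA[w] <- sumA[w] + sh[w]
    cnt <- cnt + w
  }
  peak <- sumA / cnt
  vmax <- max(a[m])
  cand <- m & (a == vmax)
  c(loc.peak_local = max(peak[cand]), loc.peak_global = max(peak[m]))
}

#' Intensity-based statistical features (18)
#'
#' @param scan_suv a \linkS4class{ScanVolume} in SUV units.
#' @param voi a \linkS4class{VoiMask}.
#' @return named numeric(18).
#' @export
computeIntensityStatistics <- function(scan_suv, voi) {
  x <- voxelValues(scan_suv)[maskArray(voi)]
  mo <- .popMoments(x)
  sk <- .skewKurt(x, mo)
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  inr <- x[x >= q[1] & x <= q[4]]
  vals <- c(
    mean = mo$mu,
    variance = mo$var,
    skewness = sk[1],
    kurtosis = sk[2],
    median = stats::median(x),
    minimum = min(x),
    p10 = q[1],
    p90 = q[4],
    maximum = max(x),
    interquartile_range = q[3] - q[2],
    range = max(x) - min(x),
    mean_absolute_deviation = mean(abs(x - mo$mu)),
    robust_mean_absolute_deviation = mean(abs(inr - mean(inr))),
    median_absolute_deviation = mean(abs(x - stats::median(x))),
    coefficient_of_variation = if (mo$mu == 0) NaN else mo$sd / mo$mu,
    quartile_coefficient_of_dispersion =
      if (q[3] + q[2] == 0) NaN else (q[3] - q[2]) / (q[3] + q[2]),
    energy = sum(x^2),
    root_mean_square = sqrt(mean(x^2)))
  stats::setNames(vals, paste0("stat.", names(vals)))
}

#' Intensity-histogram features (24)
#'
#' Computed on the fixed-bin-width grey levels 1..Ng. The IBSI histogram
#' inventory (23 features) is extended by a discretised-intensity energy
#' term (the sum of squared grey levels over voxels) to complete the
#' 24-feature family.
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @return named numeric(24).
#' @export
computeIntensityHistogram <- function(dv) {
  g <- as.numeric(dv@levels[!is.na(dv@levels)])
  ng <- dv@ng
  nI <- tabulate(g, ng)
  p <- nI / length(g)
  mo <- .popMoments(g)
  sk <- .skewKurt(g, mo)
  q <- stats::quantile(g, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  inr <- g[g >= q[1] & g <= q[4]]
  modeLev <- which(nI == max(nI))[1L]  # lowest level among tied modes
  grad <- if (ng == 1L) 0 else {
    c(nI[2L] - nI[1L],
      if (ng > 2L) (nI[3:ng] - nI[1:(ng - 2L)]) / 2,
      nI[ng] - nI[ng - 1L])
  }
  vals <- c(
    mean = mo$mu,
    variance = mo$var,
    skewness = sk[1],
    kurtosis = sk[2],
    median = stats::median(g),
    minimum = min(g),
    p10 = q[1],
    p90 = q[4],
    maximum = max(g),
    mode = as.numeric(modeLev),
    interquartile_range = q[3] - q[2],
    range = max(g) - min(g),
    mean_absolute_deviation = mean(abs(g - mo$mu)),
    robust_mean_absolute_deviation = mean(abs(inr - mean(inr))),
    median_absolute_deviation = mean(abs(g - stats::median(g))),
    coefficient_of_variation = if (mo$mu == 0) NaN else mo$sd / mo$mu,
    quartile_coefficient_of_dispersion =
      if (q[3] + q[2] == 0) NaN else (q[3] - q[2]) / (q[3] + q[2]),
    entropy = -sum(p[p > 0] * log2(p[p > 0])),
    uniformity = sum(p^2),
    maximum_gradient = max(grad),
    maximum_gradient_level = if (ng == 1L) 1 else as.numeric(which.max(grad)),
    minimum_gradient = min(grad),
    minimum_gradient_level = if (ng == 1L) 1 else as.numeric(which.min(grad)),
    energy = sum(g^2))
  stats::setNames(vals, paste0("ih.", names(vals)))
}

#' Intensity-volume histogram features (6)
#'
#' V10 and V90 are the volume fractions above intensity fractions 0.10 and
#' 0.90 of the VOI intensity range; I10 and I90 are the minimum intensities
#' of the 10\% and 90\% highest-intensity volume (k-th largest value with
#' k = ceiling(fraction * N)).
#'
#' @param scan_suv a \linkS4class{ScanVolume} in SUV units.
#' @param voi a \linkS4class{VoiMask}.
#' @return named numeric(6).
#' @export
computeIVH <- function(scan_suv, voi) {
  x <- voxelValues(scan_suv)[maskArray(voi)]
  n <- length(x)
  lo <- min(x); hi <- max(x)
  vfrac <- function(gamma) {
    if (hi == lo) return(1)
    mean(x >= lo + gamma * (hi - lo))
  }
  xs <- sort(x, decreasing = TRUE)
  ifrac <- function(p) xs[min(n, max(1L, ceiling(p * n)))]
  v10 <- vfrac(0.10); v90 <- vfrac(0.90)
  i10 <- ifrac(0.10); i90 <- ifrac(0.90)
  c(ivh.v10 = v10, ivh.v90 = v90, ivh.i10 = i10, ivh.i90 = i90,
    ivh.v10_minus_v90 = v10 - v90, ivh.i10_minus_i90 = i10 - i90)
}
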