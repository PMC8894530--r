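## Preprocessing chain: SUV conversion, isotropic resampling with trilinear
## interpolation, VOI cropping and fixed-bin-width discretisation.

#' Convert an activity image to SUV
#'
#' SUV_v = C_v [Bq/ml] * body weight [g] / activity at scan start [Bq].
#' The activity at scan start is taken as already decay-corrected.
#'
#' @param scan a \linkS4class{ScanVolume} in Bq/ml.
#' @param meta a \linkS4class{ScanMeta}.
#' @return A \linkS4class{ScanVolume} with unit \code{"SUV"}.
#' @examples
#' sv <- scanVolume(array(2000, c(2, 2, 2)))
#' voxelValues(toSUV(sv, scanMeta()))[1]   # 10
#' @export
toSUV <- function(scan, meta) {
  if (intensityUnit(scan) != "BQML")
    stop("scan is already in SUV units")
  validObject(meta)
  f <- meta@bodyWeight * 1000 / (meta@activityAtScanStart * 1e6)
  scanVolume(voxelValues(scan) * f, spacing = voxelSpacing(scan),
             origin = scan@origin, unit = "SUV")
}

#' Crop a scan and mask to the mask bounding box plus a margin
#'
#' @param scan a \linkS4class{ScanVolume}.
#' @param voi a \linkS4class{VoiMask} on the same grid.
#' @param margin_mm margin around the mask in mm.
#' @return list with cropped \code{scan} and \code{voi}.
#' @export
cropToMask <- function(scan, voi, margin_mm = 12) {
  a <- voxelValues(scan)
  m <- maskArray(voi)
  if (!identical(dim(a), dim(m))) stop("scan and mask grids differ")
  mv <- ceiling(margin_mm / voxelSpacing(scan))
  bb <- .maskBBox(m, margin = as.integer(max(mv)))
  ix <- bb$lo[1]:bb$hi[1]; iy <- bb$lo[2]:bb$hi[2]; iz <- bb$lo[3]:bb$hi[3]
  org <- scan@origin + (bb$lo - 1) * voxelSpacing(scan)
  list(scan = scanVolume(a[ix, iy, iz, drop = FALSE],
                         spacing = voxelSpacing(scan), origin = org,
                         unit = intensityUnit(scan)),
       voi = voiMask(m[ix, iy, iz, drop = FALSE], label = voi@label,
                     regionKind = voi@regionKind, patientId = voi@patientId))
}

#' Resample a scan and its VOI to an isotropic grid
#'
#' Trilinear interpolation of the image; the 0/1 mask field is interpolated
#' the same way and binarised at 0.5. The output grid is centred on the input
#' volume centre, with values defined at voxel centres.
#'
#' @param scan a \linkS4class{ScanVolume}.
#' @param voi a \linkS4class{VoiMask} on the same grid.
#' @param target_mm target isotropic voxel size in mm (default 2).
#' @return list with resampled \code{scan} and \code{voi}.
#' @export
resampleIsotropic <- function(scan, voi, target_mm = 2) {
  if (target_mm <= 0) stop("target_mm must be positive")
  a <- voxelValues(scan)
  m <- maskArray(voi)
  if (!identical(dim(a), dim(m))) stop("scan and mask grids differ")
  d <- dim(a)
  sp <- voxelSpacing(scan)
  dOut <- pmax(1L, as.integer(round(d * sp / target_mm)))
  centre <- scan@origin + (d - 1) * sp / 2
  orgOut <- centre - (dOut - 1) * target_mm / 2
  ax <- lapply(1:3, function(k) orgOut[k] + (seq_len(dOut[k]) - 1) * target_mm)
  aOut <- .trilinearGrid(a, sp, scan@origin, ax[[1]], ax[[2]], ax[[3]])
  mOut <- .trilinearGrid(array(as.numeric(m), dim = d), sp, scan@origin,
                         ax[[1]], ax[[2]], ax[[3]]) >= 0.5
  if (!any(mOut)) stop("resampled mask is empty")
  list(scan = scanVolume(aOut, spacing = rep(target_mm, 3), origin = orgOut,
                         unit = intensityUnit(scan)),
       voi = voiMask(mOut, label = voi@label, regionKind = voi@regionKind,
                     patientId = voi@patientId))
}

#' Fixed-bin-width discretisation of a SUV image within a VOI
#'
#' Grey level g_v = floor(SUV_v / bin width) + 1, anchored at 0 SUV so that
#' bins are identical across replicates (essential when comparing replicate
#' feature values).
#'
#' @param scan_suv a \linkS4class{ScanVolume} in SUV units.
#' @param voi a \linkS4class{VoiMask} on the same grid.
#' @param bin_width bin width in SUV (default 0.25).
#' @return A \linkS4class{DiscretisedVoi}.
#' @examples
#' sv <- scanVolume(array(0.6, c(2, 2, 2)), unit = "SUV")
#' m <- voiMask(array(TRUE, c(2, 2, 2)))
#' greyLevels(discretiseFBW(sv, m))[1, 1, 1]  # 3
#' @export
discretiseFBW <- function(scan_suv, voi, bin_width = 0.25) {
  if (intensityUnit(scan_suv) != "SUV") stop("scan must be in SUV units")
  if (bin_width <= 0) stop("bin_width must be positive")
  a <- voxelValues(scan_suv)
  m <- maskArray(voi)
  if (!identical(dim(a), dim(m))) stop("scan and mask grids differ")
  vals <- a[m]
  if (any(vals < 0)) stop("negative SUV inside the VOI")
  lv <- array(NA_integer_, dim = dim(a))
  lv[m] <- as.integer(floor(vals / bin_width)) + 1L
  new("DiscretisedVoi", levels = lv, binWidth = bin_width,
      ng = max(lv, na.rm = TRUE), spacing = voxelSpacing(scan_suv))
}
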