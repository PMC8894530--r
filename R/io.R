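## NIfTI and manifest I/O. Spacing travels in the NIfTI pixdim; the world
## origin travels in the JSON manifest (kept out of the qform deliberately to
## keep the writer minimal — see the vignette).

#' Write a ScanVolume to a NIfTI file
#'
#' @param scan a \linkS4class{ScanVolume}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeScanVolume <- function(scan, path) {
  img <- RNifti::asNifti(voxelValues(scan))
  RNifti::pixdim(img) <- voxelSpacing(scan)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file into a ScanVolume
#'
#' @param path NIfTI file path.
#' @param origin world coordinate of the first voxel centre (mm); NIfTI
#'   files written by this package carry their origin in the dataset
#'   manifest.
#' @param unit intensity unit of the stored values.
#' @return A \linkS4class{ScanVolume}.
#' @export
readScanVolume <- function(path, origin = c(0, 0, 0), unit = "BQML") {
  img <- RNifti::readNifti(path)
  scanVolume(array(as.numeric(img), dim = dim(img)),
             spacing = RNifti::pixdim(img)[1:3], origin = origin, unit = unit)
}

#' Write a PhantomDataset to disk
#'
#' Emits one NIfTI image per replicate, one NIfTI mask per region, and a JSON
#' manifest tying them to patients, replicate labels, conditions, metadata
#' and seeds.
#'
#' @param ds a \linkS4class{PhantomDataset}.
#' @param dir output directory (created if needed).
#' @param gz write gzipped NIfTI (default TRUE).
#' @return the manifest path, invisibly.
#' @export
writeDataset <- function(ds, dir, gz = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gz) ".nii.gz" else ".nii"
  entries <- list()
  for (p in patients(ds)) {
    g0 <- p$scans[[1]]@origin
    for (rn in names(p$scans)) {
      fn <- file.path(dir, paste0(p$patientId, "_", rn, ext))
      writeScanVolume(p$scans[[rn]], fn)
      entries[[length(entries) + 1L]] <- list(
        patient_id = p$patientId, kind = "image", replicate = rn,
        path = basename(fn), origin = g0,
        body_weight = p$meta@bodyWeight,
        injected_activity = p$meta@injectedActivity,
        activity_at_scan_start = p$meta@activityAtScanStart,
        seed = p$spec@seed)
    }
    for (mk in p$masks) {
      fn <- file.path(dir, paste0(p$patientId, "_mask_", mk@label, ext))
      writeScanVolume(scanVolume(array(as.numeric(maskArray(mk)),
                                       dim = dim(maskArray(mk))),
                                 spacing = p$scans[[1]]@spacing,
                                 origin = g0), fn)
      entries[[length(entries) + 1L]] <- list(
        patient_id = p$patientId, kind = "mask", label = mk@label,
        region_kind = mk@regionKind, path = basename(fn), origin = g0)
    }
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(seed = ds@seed, entries = entries), mpath,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mpath)
}

#' Read a written PhantomDataset back from disk
#'
#' Reconstructs the scans and masks (not the raw count volumes) from a
#' directory written by \code{\link{writeDataset}}.
#'
#' @param dir dataset directory containing \code{manifest.json}.
#' @return list of patients, each with \code{patientId}, \code{meta},
#'   \code{scans} and \code{masks}, plus an attribute \code{seed}.
#' @export
readDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  pats <- list()
  for (e in man$entries) {
    pid <- e$patient_id
    if (is.null(pats[[pid]]))
      pats[[pid]] <- list(patientId = pid, scans = list(), masks = list())
    org <- as.numeric(unlist(e$origin))
    if (e$kind == "image") {
      pats[[pid]]$scans[[e$replicate]] <-
        readScanVolume(file.path(dir, e$path), origin = org, unit = "BQML")
      pats[[pid]]$meta <- scanMeta(
        patientId = pid, bodyWeight = e$body_weight,
        injectedActivity = e$injected_activity,
        activityAtScanStart = e$activity_at_scan_start)
    } else {
      sv <- readScanVolume(file.path(dir, e$path), origin = org)
      pats[[pid]]$masks[[length(pats[[pid]]$masks) + 1L]] <-
        voiMask(voxelValues(sv) > 0.5, label = e$label,
                regionKind = e$region_kind, patientId = pid)
    }
  }
  attr(pats, "seed") <- man$seed
  pats
}
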