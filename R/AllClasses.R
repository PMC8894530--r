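#' @import methods
NULL

#' ScanVolume: a 3-D PET image with voxel geometry
#'
#' Holds a 3-D grid of voxel values in either activity concentration (Bq/ml)
#' or standardised uptake value (SUV) units, together with voxel spacing and
#' the world coordinate (mm) of the centre of the first voxel.
#'
#' @slot values 3-D numeric array of voxel values.
#' @slot spacing numeric(3), voxel spacing in mm.
#' @slot origin numeric(3), world coordinate (mm) of the first voxel centre.
#' @slot unit either \code{"BQML"} or \code{"SUV"}.
#' @export
setClass("ScanVolume",
  representation(values = "array", spacing = "numeric",
                 origin = "numeric", unit = "character"),
  prototype(spacing = c(4, 4, 4), origin = c(0, 0, 0), unit = "BQML"))

setValidity("ScanVolume", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  if (length(object@origin) != 3L) return("origin must be numeric(3)")
  if (!object@unit %in% c("BQML", "SUV"))
    return("unit must be 'BQML' or 'SUV'")
  if (any(!is.finite(object@values))) return("voxel values must be finite")
  TRUE
})

#' Construct a ScanVolume
#'
#' @param values 3-D numeric array.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin world coordinate of the first voxel centre (mm).
#' @param unit intensity unit, \code{"BQML"} or \code{"SUV"}.
#' @return A \linkS4class{ScanVolume}.
#' @examples
#' sv <- scanVolume(array(1, c(4, 4, 4)), spacing = 4)
#' @export
scanVolume <- function(values, spacing = 4, origin = c(0, 0, 0),
                       unit = "BQML") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ScanVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), unit = unit)
}

#' ScanMeta: patient-level metadata needed for SUV conversion
#'
#' @slot patientId character scalar.
#' @slot bodyWeight body weight in kg.
#' @slot injectedActivity injected activity in MBq.
#' @slot activityAtScanStart decay-corrected activity at scan start in MBq.
#' @export
setClass("ScanMeta",
  representation(patientId = "character", bodyWeight = "numeric",
                 injectedActivity = "numeric",
                 activityAtScanStart = "numeric"))

setValidity("ScanMeta", function(object) {
  if (object@bodyWeight <= 0 || object@injectedActivity <= 0 ||
      object@activityAtScanStart <= 0)
    return("weight and activities must be positive")
  TRUE
})

#' Construct a ScanMeta
#'
#' Defaults follow routine 89Zr-immuno-PET practice: 75 kg body weight,
#' 37 MBq injected, 15 MBq at scan start after several days of decay.
#'
#' @param patientId patient identifier.
#' @param bodyWeight kg.
#' @param injectedActivity MBq.
#' @param activityAtScanStart MBq (taken as already decay-corrected).
#' @return A \linkS4class{ScanMeta}.
#' @export
scanMeta <- function(patientId = "P01", bodyWeight = 75,
                     injectedActivity = 37, activityAtScanStart = 15) {
  new("ScanMeta", patientId = patientId, bodyWeight = bodyWeight,
      injectedActivity = injectedActivity,
      activityAtScanStart = activityAtScanStart)
}

#' VoiMask: a binary volume of interest on a ScanVolume grid
#'
#' @slot mask 3-D logical array.
#' @slot label region label (e.g. \code{"lesion_1"}, \code{"liver"}).
#' @slot regionKind \code{"tumour"} or \code{"background"}.
#' @slot patientId patient the region belongs to.
#' @export
setClass("VoiMask",
  representation(mask = "array", label = "character",
                 regionKind = "character", patientId = "character"))

setValidity("VoiMask", function(object) {
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a 3-D logical array")
  if (!any(object@mask)) return("mask must contain at least one voxel")
  if (!object@regionKind %in% c("tumour", "background"))
    return("regionKind must be 'tumour' or 'background'")
  TRUE
})

#' Construct a VoiMask
#'
#' @param mask 3-D logical array on the grid of its ScanVolume.
#' @param label region label.
#' @param regionKind \code{"tumour"} or \code{"background"}.
#' @param patientId patient identifier.
#' @return A \linkS4class{VoiMask}.
#' @export
voiMask <- function(mask, label = "lesion_1", regionKind = "tumour",
                    patientId = "P01") {
  new("VoiMask", mask = mask, label = label, regionKind = regionKind,
      patientId = patientId)
}

#' CountVolume: voxelwise Poisson event counts
#'
#' Image-domain surrogate for list-mode events: integer counts per voxel plus
#' a scalar calibration factor (Bq/ml per count) mapping counts back to
#' activity concentration. Splitting counts doubles the calibration so the
#' expected activity is preserved.
#'
#' @slot counts 3-D array of non-negative integers.
#' @slot calibration Bq/ml per count (positive scalar).
#' @slot spacing voxel spacing in mm.
#' @slot origin world coordinate of first voxel centre (mm).
#' @export
setClass("CountVolume",
  representation(counts = "array", calibration = "numeric",
                 spacing = "numeric", origin = "numeric"))

setValidity("CountVolume", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    return("counts must be integers")
  if (object@calibration <= 0) return("calibration must be positive")
  TRUE
})

#' DiscretisedVoi: fixed-bin-width grey levels within a VOI
#'
#' @slot levels 3-D integer array; grey level 1..Ng inside the mask, NA
#'   outside.
#' @slot binWidth bin width in SUV.
#' @slot ng maximum grey level.
#' @slot spacing voxel spacing in mm.
#' @export
setClass("DiscretisedVoi",
  representation(levels = "array", binWidth = "numeric", ng = "integer",
                 spacing = "numeric"))

setValidity("DiscretisedVoi", function(object) {
  lv <- object@levels[!is.na(object@levels)]
  if (length(lv) == 0L) return("no in-mask voxels")
  if (any(lv < 1L) || any(lv > object@ng))
    return("grey levels must lie in 1..Ng")
  if (object@ng < 1L) return("Ng must be >= 1")
  if (object@binWidth <= 0) return("binWidth must be positive")
  TRUE
})

#' LesionSpec: geometry and uptake of one synthetic lesion
#'
#' @slot centre lesion centre in mm (world coordinates).
#' @slot radii three ellipsoid semi-axes in mm.
#' @slot contrast lesion-to-background activity ratio.
#' @slot textureAmplitude SD of the correlated texture field as a fraction of
#'   the lesion mean (0 = uniform lesion).
#' @slot textureCorrelation texture correlation length in mm.
#' @export
setClass("LesionSpec",
  representation(centre = "numeric", radii = "numeric", contrast = "numeric",
                 textureAmplitude = "numeric",
                 textureCorrelation = "numeric"))

setValidity("LesionSpec", function(object) {
  if (length(object@centre) != 3L) return("centre must be numeric(3)")
  if (length(object@radii) != 3L || any(object@radii <= 0))
    return("radii must be three positive numbers")
  if (object@contrast <= 0) return("contrast must be positive")
  if (object@textureAmplitude < 0 || object@textureAmplitude >= 1)
    return("textureAmplitude must be in [0, 1)")
  if (object@textureCorrelation <= 0)
    return("textureCorrelation must be positive")
  TRUE
})

#' Construct a LesionSpec
#'
#' @param centre mm coordinates of the lesion centre.
#' @param radii ellipsoid semi-axes in mm.
#' @param contrast lesion-to-background uptake ratio.
#' @param textureAmplitude heterogeneity amplitude, fraction of lesion mean.
#' @param textureCorrelation texture correlation length in mm.
#' @return A \linkS4class{LesionSpec}.
#' @export
lesionSpec <- function(centre, radii, contrast = 6,
                       textureAmplitude = 0.2, textureCorrelation = 6) {
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  new("LesionSpec", centre = as.numeric(centre), radii = as.numeric(radii),
      contrast = contrast, textureAmplitude = textureAmplitude,
      textureCorrelation = textureCorrelation)
}

#' PhantomSpec: full description of one synthetic patient
#'
#' @slot gridShape integer(3), grid size in voxels.
#' @slot voxelSize voxel size in mm (isotropic).
#' @slot bodyRadii semi-axes of the ellipsoidal body in mm.
#' @slot organs list of organ specs (name, centre, diameter mm, uptake
#'   multiplier).
#' @slot backgroundVois list of background VOI specs (name, centre, diameter
#'   mm).
#' @slot lesions list of \linkS4class{LesionSpec}.
#' @slot backgroundActivity body background activity in Bq/ml.
#' @slot totalCounts expected total events in the full-count image.
#' @slot psfFwhm point-spread-function FWHM in mm.
#' @slot meta \linkS4class{ScanMeta}.
#' @slot seed integer seed for this patient's noise realisations.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 bodyRadii = "numeric", organs = "list",
                 backgroundVois = "list", lesions = "list",
                 backgroundActivity = "numeric", totalCounts = "numeric",
                 psfFwhm = "numeric", meta = "ScanMeta", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@gridShape < 4L)) return("gridShape too small")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (object@totalCounts <= 0) return("totalCounts must be positive")
  if (object@backgroundActivity <= 0)
    return("backgroundActivity must be positive")
  for (l in object@lesions) if (!is(l, "LesionSpec"))
    return("lesions must be LesionSpec objects")
  TRUE
})

#' PhantomDataset: a simulated multi-patient count-split study
#'
#' Per patient: the full-count image, two half-count replicates (S50p) from a
#' binomial split of the full counts, and four quarter-count replicates
#' (S25p) from splitting each half again; plus tumour and background masks
#' and metadata. Voxelwise count conservation holds exactly through both
#' splits.
#'
#' @slot patients list; each element has \code{patientId}, \code{meta},
#'   \code{spec}, \code{scans} (named list of \linkS4class{ScanVolume}:
#'   full, s50p_1, s50p_2, s25p_1..s25p_4), \code{counts} (matching
#'   \linkS4class{CountVolume}s) and \code{masks} (list of
#'   \linkS4class{VoiMask}).
#' @slot manifest data.frame keying every image (patient, replicate,
#'   condition, metadata, seed).
#' @slot seed master seed of the simulation.
#' @export
setClass("PhantomDataset",
  representation(patients = "list", manifest = "data.frame",
                 seed = "integer"))

#' MeasurementMatrix: one feature's replicate measurements at one noise level
#'
#' Rows are regions (lesions or background VOIs), columns the independent
#' count-split replicates (2 for S50p, 4 for S25p); \code{fullCount} holds
#' the matching full-count feature values.
#'
#' @slot featureId feature identifier.
#' @slot condition \code{"S50p"} or \code{"S25p"}.
#' @slot values n x k numeric matrix.
#' @slot fullCount numeric(n) full-count reference values.
#' @slot patientId character(n) patient of each row.
#' @export
setClass("MeasurementMatrix",
  representation(featureId = "character", condition = "character",
                 values = "matrix", fullCount = "numeric",
                 patientId = "character"))

setValidity("MeasurementMatrix", function(object) {
  if (!ncol(object@values) %in% c(2L, 4L))
    return("replicate count k must be 2 (S50p) or 4 (S25p)")
  if (length(object@fullCount) != nrow(object@values))
    return("fullCount must align with matrix rows")
  if (length(object@patientId) != nrow(object@values))
    return("patientId must align with matrix rows")
  TRUE
})

#' Construct a MeasurementMatrix
#'
#' @param values n x k matrix of replicate feature values.
#' @param fullCount length-n full-count feature values.
#' @param patientId length-n patient ids (defaults to one patient per row).
#' @param featureId feature identifier.
#' @param condition \code{"S50p"} or \code{"S25p"}.
#' @return A \linkS4class{MeasurementMatrix}.
#' @export
measurementMatrix <- function(values, fullCount,
                              patientId = paste0("P", seq_len(nrow(values))),
                              featureId = "feature",
                              condition = c("S50p", "S25p")[1 + (ncol(values) == 4L)]) {
  new("MeasurementMatrix", featureId = featureId, condition = condition,
      values = as.matrix(values), fullCount = as.numeric(fullCount),
      patientId = as.character(patientId))
}

#' @describeIn ScanVolume-class brief display
#' @param object a ScanVolume
#' @export
setMethod("show", "ScanVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScanVolume %dx%dx%d voxels, %s mm, unit %s, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(object@spacing, collapse = "x"),
              object@unit, min(object@values), max(object@values)))
})

#' @describeIn VoiMask-class brief display
#' @param object a VoiMask
#' @export
setMethod("show", "VoiMask", function(object) {
  cat(sprintf("VoiMask '%s' (%s, %s): %d voxels on %s grid\n",
              object@label, object@regionKind, object@patientId,
              sum(object@mask), paste(dim(object@mask), collapse = "x")))
})

#' @describeIn PhantomDataset-class brief display
#' @param object a PhantomDataset
#' @export
setMethod("show", "PhantomDataset", function(object) {
  cat(sprintf("PhantomDataset: %d patients, %d images, master seed %d\n",
              length(object@patients), nrow(object@manifest), object@seed))
})

## ---- accessors ----

#' Accessors for image containers
#'
#' @param x a \linkS4class{ScanVolume}, \linkS4class{VoiMask},
#'   \linkS4class{CountVolume} or \linkS4class{PhantomDataset}.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setMethod("voxelValues", "ScanVolume", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ScanVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "CountVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("intensityUnit", function(x) standardGeneric("intensityUnit"))
#' @rdname accessors
#' @export
setMethod("intensityUnit", "ScanVolume", function(x) x@unit)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "VoiMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("regionKind", function(x) standardGeneric("regionKind"))
#' @rdname accessors
#' @export
setMethod("regionKind", "VoiMask", function(x) x@regionKind)

#' @rdname accessors
#' @export
setGeneric("countsArray", function(x) standardGeneric("countsArray"))
#' @rdname accessors
#' @export
setMethod("countsArray", "CountVolume", function(x) x@counts)

#' @rdname accessors
#' @export
setGeneric("countCalibration", function(x) standardGeneric("countCalibration"))
#' @rdname accessors
#' @export
setMethod("countCalibration", "CountVolume", function(x) x@calibration)

#' @rdname accessors
#' @export
setGeneric("patients", function(x) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "PhantomDataset", function(x) x@patients)

#' @rdname accessors
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))
#' @rdname accessors
#' @export
setMethod("manifest", "PhantomDataset", function(x) x@manifest)

#' @rdname accessors
#' @export
setGeneric("greyLevels", function(x) standardGeneric("greyLevels"))
#' @rdname accessors
#' @export
setMethod("greyLevels", "DiscretisedVoi", function(x) x@levels)

#' @rdname accessors
#' @export
setGeneric("nGreyLevels", function(x) standardGeneric("nGreyLevels"))
#' @rdname accessors
#' @export
setMethod("nGreyLevels", "DiscretisedVoi", function(x) x@ng)
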