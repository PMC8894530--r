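## Synthetic multi-patient phantom with Poisson counts and count-split
## replicates. The count split is binomial thinning, the statistical analogue
## of separating alternate list-mode events: each half is again Poisson, the
## two halves are independent, and voxelwise counts are conserved exactly.

#' Default organ and background-VOI geometry
#'
#' Two uptake organs (a liver-like sphere at 2x background and a kidney-like
#' sphere at 1.5x) and three background VOIs: a 3 cm sphere in the liver, a
#' 2 cm sphere in the kidney and a 3 cm sphere in plain body ("muscle").
#'
#' @param scale positional scale factor (organs sit at +-scale*30 mm).
#' @return list with elements \code{organs} and \code{backgroundVois}.
#' @export
defaultOrgans <- function(scale = 1) {
  s <- scale * 30
  list(
    organs = list(
      list(name = "liver", centre = c(-s, -s * 0.6, s * 0.4), diameter = 56,
           uptake = 2.0),
      list(name = "kidney", centre = c(s, s * 0.6, -s * 0.4), diameter = 36,
           uptake = 1.5)),
    backgroundVois = list(
      list(name = "liver", centre = c(-s, -s * 0.6, s * 0.4), diameter = 30),
      list(name = "kidney", centre = c(s, s * 0.6, -s * 0.4), diameter = 20),
      list(name = "muscle", centre = c(0, s, s * 0.8), diameter = 30)))
}

#' Construct a PhantomSpec
#'
#' Defaults emulate a low-count immuno-PET acquisition: 4 mm voxels, 7 mm
#' (EARL1-like) PSF, background SUV of 1 at the default metadata (75 kg,
#' 15 MBq at scan start, i.e. 200 Bq/ml) and an expected 5e5 total events,
#' calibrated so the full-count voxel coefficient of variation inside the
#' 3 cm background spheres lies in the 15-25\% band (about 17\% in the
#' liver sphere at twice background uptake, about 25\% in plain body).
#'
#' @param gridShape grid size in voxels (scalar or length 3).
#' @param voxelSize voxel size in mm.
#' @param bodyRadii semi-axes of the ellipsoidal body (mm).
#' @param organs,backgroundVois organ / background-VOI geometry; see
#'   \code{\link{defaultOrgans}}.
#' @param lesions list of \linkS4class{LesionSpec}.
#' @param backgroundActivity body background activity in Bq/ml.
#' @param totalCounts expected total events at full count.
#' @param psfFwhm system PSF FWHM in mm.
#' @param meta \linkS4class{ScanMeta}.
#' @param seed patient seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' sp <- phantomSpec(lesions = list(lesionSpec(c(0, 0, 0), 9.3)))
#' @export
phantomSpec <- function(gridShape = 44L, voxelSize = 4,
                        bodyRadii = c(72, 72, 80),
                        organs = defaultOrgans()$organs,
                        backgroundVois = defaultOrgans()$backgroundVois,
                        lesions = list(), backgroundActivity = 200,
                        totalCounts = 5e5, psfFwhm = 7,
                        meta = scanMeta(), seed = 1L) {
  if (length(gridShape) == 1L) gridShape <- rep(gridShape, 3L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = voxelSize, bodyRadii = as.numeric(bodyRadii),
      organs = organs, backgroundVois = backgroundVois, lesions = lesions,
      backgroundActivity = backgroundActivity, totalCounts = totalCounts,
      psfFwhm = psfFwhm, meta = meta, seed = as.integer(seed))
}

.specGeometry <- function(spec) {
  d <- spec@gridShape
  sp <- rep(spec@voxelSize, 3L)
  org <- -(d - 1) * sp / 2  # grid centred on the world origin
  list(d = d, spacing = sp, origin = org)
}

.sphereMask <- function(g, centre, diameter) {
  .ellipsoidMask(g$d, g$spacing, g$origin, centre, rep(diameter / 2, 3L))
}

## Correlated Gaussian texture field with unit SD inside the lesion.
.textureField <- function(g, corr_mm, seed) {
  w <- .withSeed(seed, array(stats::rnorm(prod(g$d)), dim = g$d))
  f <- .gaussSmooth(w, corr_mm, g$spacing)
  s <- stats::sd(f)
  if (s == 0) return(array(0, dim = g$d))
  f / s
}

#' Generate the activity map and VOI masks for one synthetic patient
#'
#' Builds an ellipsoidal body at the background activity, adds organ uptake
#' regions, carves ellipsoidal lesions whose interior activity is
#' \code{background * contrast * (1 + texture)} with a correlated Gaussian
#' texture field, and finally blurs with the system PSF. Lesion and
#' background-VOI masks are the pre-PSF geometric interiors.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param psf apply the PSF blur (set \code{FALSE} to inspect the pre-PSF
#'   piecewise-constant map).
#' @return list with \code{scan} (\linkS4class{ScanVolume}, Bq/ml) and
#'   \code{masks} (list of \linkS4class{VoiMask}: lesions then background
#'   VOIs).
#' @examples
#' out <- generateActivityMap(phantomSpec())
#' out$scan
#' @export
generateActivityMap <- function(spec, psf = TRUE) {
  validObject(spec)
  g <- .specGeometry(spec)
  body <- .ellipsoidMask(g$d, g$spacing, g$origin, c(0, 0, 0), spec@bodyRadii)
  act <- array(0, dim = g$d)
  act[body] <- spec@backgroundActivity
  for (o in spec@organs) {
    m <- .sphereMask(g, o$centre, o$diameter) & body
    act[m] <- spec@backgroundActivity * o$uptake
  }
  masks <- list()
  lesTotal <- array(FALSE, dim = g$d)
  pid <- spec@meta@patientId
  for (i in seq_along(spec@lesions)) {
    l <- spec@lesions[[i]]
    validObject(l)
    m <- .ellipsoidMask(g$d, g$spacing, g$origin, l@centre, l@radii)
    if (!any(m)) stop("lesion ", i, " covers no voxel")
    if (any(m & !body)) stop("lesion ", i, " extends outside the body")
    if (any(m & lesTotal)) stop("lesion ", i, " overlaps another lesion")
    lesTotal <- lesTotal | m
    base <- spec@backgroundActivity * l@contrast
    if (l@textureAmplitude > 0) {
      tf <- .textureField(g, l@textureCorrelation,
                          .deriveSeed(spec@seed, pid, "texture", i))
      mod <- pmax(1 + l@textureAmplitude * tf[m], 0.05)
      act[m] <- base * mod
    } else {
      act[m] <- base
    }
    masks[[length(masks) + 1L]] <-
      voiMask(m, label = paste0("lesion_", i), regionKind = "tumour",
              patientId = pid)
  }
  for (b in spec@backgroundVois) {
    m <- .sphereMask(g, b$centre, b$diameter) & body
    if (any(m & lesTotal)) stop("background VOI '", b$name,
                                "' overlaps a lesion")
    masks[[length(masks) + 1L]] <-
      voiMask(m, label = b$name, regionKind = "background", patientId = pid)
  }
  if (psf) act <- .gaussSmooth(act, spec@psfFwhm, g$spacing)
  list(scan = scanVolume(act, spacing = g$spacing, origin = g$origin,
                         unit = "BQML"),
       masks = masks)
}

#' Realise the full-count Poisson image
#'
#' Draws voxelwise independent Poisson counts with means proportional to the
#' activity map, scaled so the expected grand total equals
#' \code{spec@totalCounts}. The returned calibration (Bq/ml per count) maps
#' counts back to activity concentration.
#'
#' @param activity a \linkS4class{ScanVolume} in Bq/ml.
#' @param spec the \linkS4class{PhantomSpec} (for \code{totalCounts}).
#' @param seed RNG seed.
#' @return A \linkS4class{CountVolume}.
#' @export
realizeFullCount <- function(activity, spec, seed = spec@seed) {
  a <- voxelValues(activity)
  if (any(a < 0)) stop("activity must be non-negative")
  if (spec@totalCounts <= 0) stop("totalCounts must be positive")
  tot <- sum(a)
  if (tot == 0) {
    counts <- array(0, dim = dim(a))
    calib <- 1
  } else {
    calib <- tot / spec@totalCounts
    lam <- a / calib
    counts <- .withSeed(seed,
                        array(stats::rpois(length(lam), lam), dim = dim(a)))
  }
  new("CountVolume", counts = counts, calibration = calib,
      spacing = voxelSpacing(activity), origin = activity@origin)
}

#' Split a count image into two independent halves
#'
#' Per voxel, one half is Binomial(c, 1/2) and the other the remainder, so
#' counts are conserved exactly and each half is an independent Poisson field
#' with half the mean (thinning property). Each half's calibration is doubled
#' so it represents a scan acquired with 50\% of the injected activity.
#'
#' @param cv a \linkS4class{CountVolume}.
#' @param seed RNG seed.
#' @return list of two \linkS4class{CountVolume}s.
#' @export
splitCounts <- function(cv, seed = 1L) {
  c0 <- cv@counts
  c1 <- .withSeed(seed,
                  array(stats::rbinom(length(c0), as.integer(c0), 0.5),
                        dim = dim(c0)))
  mk <- function(cc) new("CountVolume", counts = cc,
                         calibration = cv@calibration * 2,
                         spacing = cv@spacing, origin = cv@origin)
  list(mk(c1), mk(c0 - c1))
}

#' Convert a CountVolume back to an activity image
#'
#' @param cv a \linkS4class{CountVolume}.
#' @param postSmoothFwhm optional Gaussian smoothing (mm FWHM, default off)
#'   mimicking correlated reconstruction noise.
#' @return A \linkS4class{ScanVolume} in Bq/ml.
#' @export
countsToActivity <- function(cv, postSmoothFwhm = 0) {
  a <- cv@counts * cv@calibration
  if (postSmoothFwhm > 0) a <- .gaussSmooth(a, postSmoothFwhm, cv@spacing)
  scanVolume(a, spacing = cv@spacing, origin = cv@origin, unit = "BQML")
}

#' Build a complete count-split dataset
#'
#' For every patient: the full-count image, two S50p half-count replicates
#' (split of the full counts) and four S25p quarter-count replicates (split
#' of each half). All seven images are converted to the activity scale via
#' their calibrations, so replicate differences are due to counting noise
#' only.
#'
#' @param specList list of \linkS4class{PhantomSpec}, one per patient.
#' @param seed master seed; per-patient and per-stage seeds are derived
#'   deterministically from it.
#' @param postSmoothFwhm optional post-split smoothing in mm (default 0).
#' @return A \linkS4class{PhantomDataset}.
#' @examples
#' ds <- buildDataset(list(phantomSpec(gridShape = 24L,
#'   lesions = list(lesionSpec(c(0, 0, 0), 10)))), seed = 1)
#' ds
#' @export
buildDataset <- function(specList, seed = 1L, postSmoothFwhm = 0) {
  if (length(specList) < 1L) stop("need at least one patient")
  ids <- vapply(specList, function(s) s@meta@patientId, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient IDs: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  reps <- c("full", "s50p_1", "s50p_2", "s25p_1", "s25p_2", "s25p_3", "s25p_4")
  cond <- c("full", "S50p", "S50p", "S25p", "S25p", "S25p", "S25p")
  pats <- vector("list", length(specList))
  man <- list()
  for (i in seq_along(specList)) {
    spec <- specList[[i]]
    pid <- ids[i]
    am <- generateActivityMap(spec)
    cvFull <- realizeFullCount(am$scan, spec,
                               seed = .deriveSeed(seed, pid, "full"))
    h <- splitCounts(cvFull, seed = .deriveSeed(seed, pid, "s50"))
    q1 <- splitCounts(h[[1]], seed = .deriveSeed(seed, pid, "s25a"))
    q2 <- splitCounts(h[[2]], seed = .deriveSeed(seed, pid, "s25b"))
    counts <- list(cvFull, h[[1]], h[[2]], q1[[1]], q1[[2]], q2[[1]], q2[[2]])
    names(counts) <- reps
    scans <- lapply(counts, countsToActivity, postSmoothFwhm = postSmoothFwhm)
    pats[[i]] <- list(patientId = pid, meta = spec@meta, spec = spec,
                      scans = scans, counts = counts, masks = am$masks)
    man[[i]] <- data.frame(
      patient_id = pid, replicate = reps, condition = cond,
      body_weight = spec@meta@bodyWeight,
      injected_activity = spec@meta@injectedActivity,
      activity_at_scan_start = spec@meta@activityAtScanStart,
      seed = .deriveSeed(seed, pid, "full"), stringsAsFactors = FALSE)
  }
  names(pats) <- ids
  new("PhantomDataset", patients = pats,
      manifest = do.call(rbind, man), seed = as.integer(seed))
}

#' Study-condition phantom specifications
#'
#' The canonical synthetic study: several patients with 1-10 lesions each,
#' lesion volumes lognormal with median 6.3 ml clipped to [1, 30] ml,
#' contrast lognormal with median 6, mild ellipsoidal anisotropy, texture
#' amplitude 0.2 with 6 mm correlation length. Lesion centres are placed by
#' rejection sampling so every lesion lies inside the body and clear of
#' organs, background VOIs and other lesions.
#'
#' @param nPatients number of patients.
#' @param lesionsPerPatient integer vector (recycled) of lesion counts.
#' @param seed master seed; placement seeds are derived per patient.
#' @param ... passed to \code{\link{phantomSpec}} (e.g. \code{totalCounts}).
#' @return list of \linkS4class{PhantomSpec}.
#' @examples
#' specs <- studyPhantomSpecs(2, c(1, 2), seed = 7)
#' length(specs[[2]]@lesions)
#' @export
studyPhantomSpecs <- function(nPatients = 4,
                              lesionsPerPatient = c(2, 3, 3, 4),
                              seed = 1L, ...) {
  nles <- rep_len(lesionsPerPatient, nPatients)
  specs <- vector("list", nPatients)
  for (p in seq_len(nPatients)) {
    pid <- sprintf("P%02d", p)
    base <- phantomSpec(meta = scanMeta(patientId = pid),
                        seed = .deriveSeed(seed, pid, "phantom"), ...)
    g <- .specGeometry(base)
    occupied <- array(FALSE, dim = g$d)
    body <- .ellipsoidMask(g$d, g$spacing, g$origin, c(0, 0, 0),
                           base@bodyRadii)
    for (o in base@organs)
      occupied <- occupied | (.sphereMask(g, o$centre, o$diameter) & body)
    for (b in base@backgroundVois)
      occupied <- occupied | (.sphereMask(g, b$centre, b$diameter) & body)
    lesions <- .withSeed(.deriveSeed(seed, pid, "lesions"), {
      out <- list()
      for (j in seq_len(nles[p])) {
        vol <- min(max(stats::rlnorm(1, log(6.3), 0.6), 1), 30)  # ml
        r0 <- (3 * vol * 1000 / (4 * pi))^(1 / 3)
        ax <- r0 * stats::runif(3, 0.85, 1.18)
        ax <- ax * (vol * 1000 / (4 / 3 * pi * prod(ax)))^(1 / 3)
        contrast <- min(max(stats::rlnorm(1, log(6), 0.4), 2), 15)
        placed <- FALSE
        for (try in 1:400) {
          ctr <- stats::runif(3, -0.7, 0.7) * base@bodyRadii
          m <- .ellipsoidMask(g$d, g$spacing, g$origin, ctr, ax)
          if (any(m) && !any(m & !body) && !any(m & occupied)) {
            occupied <- occupied | m
            out[[j]] <- lesionSpec(ctr, ax, contrast = contrast)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place lesion ", j, " for ", pid)
      }
      out
    })
    specs[[p]] <- phantomSpec(meta = scanMeta(patientId = pid),
                              lesions = lesions,
                              seed = .deriveSeed(seed, pid, "phantom"), ...)
  }
  specs
}
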