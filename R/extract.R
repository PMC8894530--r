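## The 458-feature inventory and the extraction pipeline:
## SUV conversion -> crop -> 2 mm isotropic resampling -> FBW discretisation
## -> all ten feature families.

.STAT_NAMES <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
  "p90", "maximum", "interquartile_range", "range",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation",
  "quartile_coefficient_of_dispersion", "energy", "root_mean_square")

.IH_NAMES <- c(
  "mean", "variance", "skewness", "kurtosis", "median", "minimum", "p10",
  "p90", "maximum", "mode", "interquartile_range", "range",
  "mean_absolute_deviation", "robust_mean_absolute_deviation",
  "median_absolute_deviation", "coefficient_of_variation",
  "quartile_coefficient_of_dispersion", "entropy", "uniformity",
  "maximum_gradient", "maximum_gradient_level", "minimum_gradient",
  "minimum_gradient_level", "energy")

.IVH_NAMES <- c("v10", "v90", "i10", "i90", "v10_minus_v90", "i10_minus_i90")
.LOC_NAMES <- c("peak_local", "peak_global")

#' The radiomic feature catalogue
#'
#' All 458 features in ten families: local intensity (2), intensity
#' statistics (18), intensity histogram (24), intensity-volume histogram
#' (6), GLCM (25 features x 6 aggregations = 150), GLRLM (16 x 6 = 96),
#' GLSZM (16 x 3 = 48), GLDZM (16 x 3 = 48), NGTDM (5 x 3 = 15) and NGLDM
#' (17 x 3 = 51).
#'
#' @return data.frame with columns \code{family}, \code{feature},
#'   \code{aggregation} (NA for intensity families) and \code{id}, in the
#'   canonical extraction order.
#' @examples
#' nrow(featureCatalogue())  # 458
#' table(featureCatalogue()$family)
#' @export
featureCatalogue <- function() {
  block <- function(family, feats, aggs = NA_character_) {
    g <- expand.grid(feature = feats, aggregation = aggs,
                     stringsAsFactors = FALSE)
    data.frame(family = family, feature = g$feature,
               aggregation = g$aggregation,
               id = ifelse(is.na(g$aggregation),
                           paste(family, g$feature, sep = "."),
                           paste(family, g$feature, g$aggregation,
                                 sep = ".")),
               stringsAsFactors = FALSE)
  }
  rbind(block("loc", .LOC_NAMES),
        block("stat", .STAT_NAMES),
        block("ih", .IH_NAMES),
        block("ivh", .IVH_NAMES),
        block("glcm", .GLCM_NAMES, .AGG6),
        block("glrlm", .GLRLM_NAMES, .AGG6),
        block("glszm", .GLSZM_NAMES, .AGG3),
        block("gldzm", .GLDZM_NAMES, .AGG3),
        block("ngtdm", .NGTDM_NAMES, .AGG3),
        block("ngldm", .NGLDM_NAMES, .AGG3))
}

#' Extraction settings
#'
#' @param binWidth fixed bin width in SUV (default 0.25).
#' @param targetSpacing isotropic resampling target in mm (default 2).
#' @param marginMm crop margin around the VOI in mm (wide enough for the
#'   1 cm^3 intensity-peak sphere).
#' @return a named list of settings.
#' @export
radiomicsSettings <- function(binWidth = 0.25, targetSpacing = 2,
                              marginMm = 12) {
  list(binWidth = binWidth, targetSpacing = targetSpacing,
       marginMm = marginMm)
}

#' Extract the full 458-feature vector for one VOI
#'
#' Runs the preprocessing chain (SUV conversion if the scan is in Bq/ml,
#' crop, isotropic resampling with trilinear interpolation of image and
#' mask, fixed-bin-width discretisation anchored at 0 SUV) and computes all
#' ten feature families. Deterministic: identical inputs give bit-identical
#' output.
#'
#' @param scan a \linkS4class{ScanVolume} (Bq/ml or SUV).
#' @param voi a \linkS4class{VoiMask} on the same grid.
#' @param meta a \linkS4class{ScanMeta} (needed when \code{scan} is Bq/ml).
#' @param settings see \code{\link{radiomicsSettings}}.
#' @return named numeric(458) in catalogue order.
#' @export
extractAllFeatures <- function(scan, voi, meta = scanMeta(),
                               settings = radiomicsSettings()) {
  res <- tryCatch({
    if (intensityUnit(scan) == "BQML") scan <- toSUV(scan, meta)
    cr <- cropToMask(scan, voi, margin_mm = settings$marginMm)
    rs <- resampleIsotropic(cr$scan, cr$voi,
                            target_mm = settings$targetSpacing)
    dv <- discretiseFBW(rs$scan, rs$voi, bin_width = settings$binWidth)
    v <- c(computeLocalIntensity(rs$scan, rs$voi),
           computeIntensityStatistics(rs$scan, rs$voi),
           computeIntensityHistogram(dv),
           computeIVH(rs$scan, rs$voi),
           computeGlcmFeatures(dv),
           computeGlrlmFeatures(dv),
           computeZoneFeatures(dv),
           computeNeighbourhoodFeatures(dv))
    v
  }, error = function(e) {
    stop("feature extraction failed for region '", voi@label, "' (",
         voi@patientId, "): ", conditionMessage(e), call. = FALSE)
  })
  cat_ids <- featureCatalogue()$id
  if (!identical(names(res), cat_ids))
    res <- res[cat_ids]
  stopifnot(length(res) == 458L)
  res
}

#' Extract features for every region and replicate of a dataset
#'
#' @param ds a \linkS4class{PhantomDataset} (or the list returned by
#'   \code{\link{readDataset}}).
#' @param settings see \code{\link{radiomicsSettings}}.
#' @param verbose print progress.
#' @return A \code{SummarizedExperiment}: assay \code{"features"} is a
#'   458 x (regions x replicates) matrix, \code{rowData} the feature
#'   catalogue, \code{colData} the keys (\code{patient_id},
#'   \code{region_id}, \code{region_kind}, \code{condition},
#'   \code{replicate}).
#' @export
extractDataset <- function(ds, settings = radiomicsSettings(),
                           verbose = FALSE) {
  pats <- if (is(ds, "PhantomDataset")) patients(ds) else ds
  cat_df <- featureCatalogue()
  cols <- list(); vals <- list()
  for (p in pats) {
    for (mk in p$masks) {
      rid <- paste(p$patientId, mk@label, sep = ":")
      for (rn in names(p$scans)) {
        if (verbose) message("extracting ", rid, " / ", rn)
        fv <- extractAllFeatures(p$scans[[rn]], mk, p$meta, settings)
        cols[[length(cols) + 1L]] <- data.frame(
          patient_id = p$patientId, region_id = rid,
          region_kind = mk@regionKind,
          condition = c(full = "full", s50p_1 = "S50p", s50p_2 = "S50p",
                        s25p_1 = "S25p", s25p_2 = "S25p", s25p_3 = "S25p",
                        s25p_4 = "S25p")[[rn]],
          replicate = rn, stringsAsFactors = FALSE)
        vals[[length(vals) + 1L]] <- fv
      }
    }
  }
  m <- do.call(cbind, vals)
  cd <- do.call(rbind, cols)
  colnames(m) <- paste(cd$region_id, cd$replicate, sep = "/")
  rownames(cd) <- colnames(m)
  rownames(m) <- cat_df$id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(cat_df, row.names = cat_df$id),
    colData = S4Vectors::DataFrame(cd))
}

#' Write a feature table to CSV in long format
#'
#' Columns: patient_id, region_id, region_kind, condition, replicate,
#' family, feature, aggregation, value.
#'
#' @param se SummarizedExperiment from \code{\link{extractDataset}}.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatureTable <- function(se, path) {
  m <- SummarizedExperiment::assay(se, "features")
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  long <- data.frame(
    cd[rep(seq_len(nrow(cd)), each = nrow(m)), , drop = FALSE],
    rd[rep(seq_len(nrow(rd)), times = nrow(cd)), c("family", "feature",
                                                   "aggregation")],
    value = as.numeric(m), row.names = NULL)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format feature table CSV back into a SummarizedExperiment
#'
#' @param path CSV written by \code{\link{writeFeatureTable}}.
#' @return A SummarizedExperiment matching \code{\link{extractDataset}}
#'   output.
#' @export
readFeatureTable <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  cat_df <- featureCatalogue()
  key <- paste(long$region_id, long$replicate, sep = "/")
  ids <- ifelse(is.na(long$aggregation) | long$aggregation == "",
                paste(long$family, long$feature, sep = "."),
                paste(long$family, long$feature, long$aggregation, sep = "."))
  ucols <- !duplicated(key)
  m <- matrix(NA_real_, nrow = nrow(cat_df), ncol = sum(ucols),
              dimnames = list(cat_df$id, key[ucols]))
  m[cbind(match(ids, cat_df$id), match(key, key[ucols]))] <- long$value
  cd <- long[ucols, c("patient_id", "region_id", "region_kind", "condition",
                      "replicate")]
  rownames(cd) <- key[ucols]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(cat_df, row.names = cat_df$id),
    colData = S4Vectors::DataFrame(cd))
}
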