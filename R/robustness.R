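## Precision (ICC) and noise-induced bias (SDM) of radiomic features across
## count-split replicates, with lesion subsampling, four-level
## categorisation and Fisher's exact comparison of category distributions
## between noise levels.

#' Two-way absolute-agreement single-measurement ICC
#'
#' ICC(A,1): replicate images are the raters (fixed), regions the subjects
#' (random). From the two-way ANOVA mean squares,
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)). May be
#' negative; NaN when the total variance is zero.
#'
#' @param Y numeric n x k matrix (n regions, k replicates).
#' @return the ICC estimate.
#' @examples
#' iccAbsoluteAgreement(cbind(1:5, 1:5))  # 1
#' @export
iccAbsoluteAgreement <- function(Y) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns")
  if (any(!is.finite(Y))) return(NaN)
  gm <- mean(Y)
  rm_ <- rowMeans(Y); cm <- colMeans(Y)
  sst <- sum((Y - gm)^2)
  if (sst == 0) return(NaN)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (den == 0) return(NaN)
  (msr - mse) / den
}

## Vectorised ICC over an n x k x F array (one slab per feature).
.iccAll <- function(Y) {
  n <- dim(Y)[1L]; k <- dim(Y)[2L]; nf <- dim(Y)[3L]
  flat <- matrix(Y, nrow = n * k)
  gm <- colMeans(flat)
  rm_ <- apply(Y, c(1L, 3L), mean)           # n x F
  cm <- apply(Y, c(2L, 3L), mean)            # k x F
  sst <- colSums((flat - rep(gm, each = n * k))^2)
  ssr <- k * colSums((rm_ - rep(gm, each = n))^2)
  ssc <- n * colSums((cm - rep(gm, each = k))^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  out <- (msr - mse) / den
  out[sst == 0 | den == 0] <- NaN
  out
}

#' Similarity distance metric (SDM)
#'
#' Accuracy statistic for noise-induced bias: for each replicate column r_j,
#' sigma_f^2 / (mean_i (f_i - r_ij)^2 + sigma_f^2), averaged over the m
#' replicates, where sigma_f^2 is the (sample) variance of the full-count
#' feature values f across the n regions. Ranges from 0 (bias-dominated) to
#' 1 (no bias).
#'
#' @param f numeric(n): full-count feature values per region.
#' @param R n x m matrix of count-split replicate values (m = 2 for S50p,
#'   4 for S25p).
#' @return the SDM in [0, 1]; NaN on non-finite input.
#' @examples
#' sdm(c(1, 2, 3), cbind(c(1.1, 2.1, 3.1)))  # 1 / 1.01
#' @export
sdm <- function(f, R) {
  R <- as.matrix(R)
  if (length(f) != nrow(R)) stop("f must align with the rows of R")
  if (length(f) < 2L) stop("need at least 2 regions")
  if (any(!is.finite(f)) || any(!is.finite(R))) return(NaN)
  s2 <- stats::var(f)
  d2 <- colMeans((f - R)^2)
  terms <- ifelse(d2 + s2 == 0, 1, s2 / (d2 + s2))
  mean(terms)
}

## Vectorised SDM: F full-count matrix n x nf, R array n x m x nf.
.sdmAll <- function(Fm, R) {
  n <- nrow(Fm); nf <- ncol(Fm); m <- dim(R)[2L]
  s2 <- apply(Fm, 2L, stats::var)
  out <- numeric(nf)
  for (j in seq_len(m)) {
    d2 <- colMeans((Fm - R[, j, ])^2)
    t_ <- ifelse(d2 + s2 == 0, 1, s2 / (d2 + s2))
    out <- out + t_
  }
  out <- out / m
  bad <- apply(Fm, 2L, function(v) any(!is.finite(v))) |
    apply(R, 3L, function(v) any(!is.finite(v)))
  out[bad] <- NaN
  out
}

#' Subsampling scheme
#'
#' Random sampling of lesions without replacement: at each iteration every
#' patient contributes at most \code{maxPerPatient} of its lesions, to
#' avoid imbalance from patients with many lesions.
#'
#' @param iterations number of iterations (default 100).
#' @param maxPerPatient per-patient lesion cap (default 3).
#' @param seed RNG seed for the subset draws.
#' @return a named list.
#' @export
subsampleScheme <- function(iterations = 100, maxPerPatient = 3, seed = 1L) {
  stopifnot(iterations >= 1, maxPerPatient >= 1)
  list(iterations = as.integer(iterations),
       maxPerPatient = as.integer(maxPerPatient), seed = as.integer(seed))
}

#' Draw the subsample iterations
#'
#' @param regions data.frame with columns \code{region_id} and
#'   \code{patient_id}, one row per region.
#' @param scheme see \code{\link{subsampleScheme}}.
#' @param cap per-patient cap; defaults to the scheme's
#'   \code{maxPerPatient}. Use \code{Inf} for background regions (no cap).
#' @return list of \code{iterations} character vectors of region ids.
#' @export
subsampleIterations <- function(regions, scheme = subsampleScheme(),
                                cap = scheme$maxPerPatient) {
  if (nrow(regions) == 0L) stop("no regions to subsample")
  byPat <- split(regions$region_id, regions$patient_id)
  .withSeed(scheme$seed, {
    lapply(seq_len(scheme$iterations), function(i) {
      unlist(lapply(byPat, function(ids) {
        if (length(ids) <= cap) ids
        else ids[sample.int(length(ids), cap)]
      }), use.names = FALSE)
    })
  })
}

#' Categorise an ICC or SDM value
#'
#' poor [0, 0.5) (negative values included), moderate [0.5, 0.75),
#' good [0.75, 0.9), excellent [0.9, 1]; NaN is uncategorised (NA).
#'
#' @param x numeric vector of metric values.
#' @return factor with levels poor < moderate < good < excellent.
#' @examples
#' categoriseMetric(c(0.9, 0.75, -0.2))
#' @export
categoriseMetric <- function(x) {
  out <- cut(x, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
             labels = c("poor", "moderate", "good", "excellent"))
  out[!is.finite(x)] <- NA
  out
}

.CATEGORIES <- c("poor", "moderate", "good", "excellent")

## Core iteration engine for one (region kind, condition) stratum: computes
## per-iteration ICC/SDM for all features at once and aggregates.
.summariseStratum <- function(Fm, Rarr, regions, subsets, scheme) {
  nf <- ncol(Fm)
  iccIt <- matrix(NA_real_, length(subsets), nf)
  sdmIt <- matrix(NA_real_, length(subsets), nf)
  for (it in seq_along(subsets)) {
    idx <- match(subsets[[it]], regions)
    if (length(idx) < 2L) next
    iccIt[it, ] <- .iccAll(Rarr[idx, , , drop = FALSE])
    sdmIt[it, ] <- .sdmAll(Fm[idx, , drop = FALSE],
                           Rarr[idx, , , drop = FALSE])
  }
  aggOne <- function(M) {
    nValid <- colSums(is.finite(M))
    ok <- nValid >= length(subsets) / 2    # NaN result if < 50% valid
    mn <- apply(M, 2L, function(v) mean(v[is.finite(v)]))
    sdv <- apply(M, 2L, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2L) 0 else stats::sd(v)
    })
    ci <- apply(M, 2L, function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) c(NaN, NaN)
      else stats::quantile(v, c(0.025, 0.975), names = FALSE)
    })
    mn[!ok] <- NaN
    list(mean = mn, sd = sdv, lo = ci[1L, ], hi = ci[2L, ], nValid = nValid)
  }
  list(icc = aggOne(iccIt), sdm = aggOne(sdmIt))
}

#' Summarise one feature's robustness from a MeasurementMatrix
#'
#' Per subsample iteration the ICC (replicate matrix restricted to the
#' subset) and the SDM (full-count subset vs replicate subset) are
#' computed; the summary is their mean, SD and percentile 95\% CI over
#' iterations, plus categories from the means.
#'
#' @param mm a \linkS4class{MeasurementMatrix}.
#' @param scheme see \code{\link{subsampleScheme}}.
#' @param cap per-patient cap (default the scheme's; \code{Inf} disables).
#' @return one-row data.frame with ICC and SDM summaries and categories.
#' @export
summariseFeature <- function(mm, scheme = subsampleScheme(),
                             cap = scheme$maxPerPatient) {
  validObject(mm)
  regions <- paste0("r", seq_len(nrow(mm@values)))
  subsets <- subsampleIterations(
    data.frame(region_id = regions, patient_id = mm@patientId),
    scheme, cap = cap)
  Fm <- matrix(mm@fullCount, ncol = 1L)
  Rarr <- array(mm@values, dim = c(dim(mm@values), 1L))
  st <- .summariseStratum(Fm, Rarr, regions, subsets, scheme)
  data.frame(
    feature_id = mm@featureId, condition = mm@condition,
    icc_mean = st$icc$mean, icc_sd = st$icc$sd,
    icc_lo = st$icc$lo, icc_hi = st$icc$hi,
    icc_category = as.character(categoriseMetric(st$icc$mean)),
    sdm_mean = st$sdm$mean, sdm_sd = st$sdm$sd,
    sdm_lo = st$sdm$lo, sdm_hi = st$sdm$hi,
    sdm_category = as.character(categoriseMetric(st$sdm$mean)),
    n_valid_icc = st$icc$nValid, n_valid_sdm = st$sdm$nValid,
    stringsAsFactors = FALSE)
}

#' Robustness analysis of a full feature table
#'
#' For every feature, region kind (tumour / background) and condition (S50p
#' with k = 2 replicates, S25p with k = 4), computes the subsampled ICC and
#' SDM summaries and categories. The per-patient lesion cap applies to
#' tumour regions only; background VOIs (one per organ per patient) enter
#' uncapped. Iteration subsets are drawn once per region kind and shared by
#' all features and both conditions.
#'
#' @param se SummarizedExperiment from \code{\link{extractDataset}}.
#' @param scheme see \code{\link{subsampleScheme}}.
#' @param conditions noise levels to analyse.
#' @return data.frame, one row per feature x region kind x condition.
#' @export
analyseRobustness <- function(se, scheme = subsampleScheme(),
                              conditions = c("S50p", "S25p")) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  rd <- as.data.frame(SummarizedExperiment::rowData(se))
  m <- SummarizedExperiment::assay(se, "features")
  reps <- list(S50p = c("s50p_1", "s50p_2"),
               S25p = c("s25p_1", "s25p_2", "s25p_3", "s25p_4"))
  out <- list()
  for (kind in sort(unique(cd$region_kind))) {
    sub <- cd[cd$region_kind == kind, ]
    regTbl <- unique(sub[, c("region_id", "patient_id")])
    cap <- if (kind == "tumour") scheme$maxPerPatient else Inf
    subsets <- subsampleIterations(regTbl, scheme, cap = cap)
    for (cond in conditions) {
      rlabs <- reps[[cond]]
      colFor <- function(rep_) {
        rownames(sub)[match(paste(regTbl$region_id, rep_, sep = "/"),
                            paste(sub$region_id, sub$replicate, sep = "/"))]
      }
      Fm <- t(m[, colFor("full"), drop = FALSE])        # regions x features
      Rarr <- array(NA_real_,
                    dim = c(nrow(regTbl), length(rlabs), nrow(m)))
      for (j in seq_along(rlabs))
        Rarr[, j, ] <- t(m[, colFor(rlabs[j]), drop = FALSE])
      st <- .summariseStratum(Fm, Rarr, regTbl$region_id, subsets, scheme)
      out[[length(out) + 1L]] <- data.frame(
        feature_id = rd$id, family = rd$family, feature = rd$feature,
        aggregation = rd$aggregation, region_kind = kind, condition = cond,
        n_regions = nrow(regTbl),
        icc_mean = st$icc$mean, icc_sd = st$icc$sd,
        icc_lo = st$icc$lo, icc_hi = st$icc$hi,
        icc_category = as.character(categoriseMetric(st$icc$mean)),
        sdm_mean = st$sdm$mean, sdm_sd = st$sdm$sd,
        sdm_lo = st$sdm$lo, sdm_hi = st$sdm$hi,
        sdm_category = as.character(categoriseMetric(st$sdm$mean)),
        n_valid_icc = st$icc$nValid, n_valid_sdm = st$sdm$nValid,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Compare category distributions between noise levels
#'
#' Fisher's exact test on the 4 x 2 contingency table of category counts
#' (poor/moderate/good/excellent) at S50p vs S25p. Exact network
#' enumeration for small tables; Monte-Carlo estimation (fixed seed) above
#' \code{mcThreshold} total counts.
#'
#' @param counts_s50p,counts_s25p non-negative integer 4-vectors of
#'   category counts.
#' @param mcThreshold total count above which the Monte-Carlo p-value is
#'   used.
#' @param B Monte-Carlo replicates.
#' @param seed Monte-Carlo seed.
#' @return list with \code{p.value}, \code{method} and the \code{table}.
#' @examples
#' compareCategoryDistributions(c(10, 10, 10, 10), c(20, 20, 20, 20))$p.value
#' @export
compareCategoryDistributions <- function(counts_s50p, counts_s25p,
                                         mcThreshold = 5000, B = 1e5,
                                         seed = 1L) {
  stopifnot(length(counts_s50p) == 4L, length(counts_s25p) == 4L,
            all(counts_s50p >= 0), all(counts_s25p >= 0))
  tab <- cbind(S50p = counts_s50p, S25p = counts_s25p)
  rownames(tab) <- .CATEGORIES
  if (sum(tab) == 0) stop("all-zero contingency table")
  keep <- rowSums(tab) > 0
  t2 <- tab[keep, , drop = FALSE]
  if (nrow(t2) < 2L || any(colSums(t2) == 0))
    return(list(p.value = 1, method = "degenerate", table = tab))
  if (sum(t2) <= mcThreshold) {
    ft <- stats::fisher.test(t2, workspace = 2e7)
    list(p.value = ft$p.value, method = "exact", table = tab)
  } else {
    ft <- .withSeed(seed,
                    stats::fisher.test(t2, simulate.p.value = TRUE, B = B))
    list(p.value = ft$p.value, method = "monte-carlo", table = tab)
  }
}

#' Per-family category percentages and robust feature sets
#'
#' For each region kind, condition, metric (ICC / SDM) and feature family:
#' the percentage of features in each category (uncategorised features
#' reported separately via \code{n_uncategorised}). Also returns the robust
#' feature sets: features with excellent ICC and SDM per condition, and
#' features good-or-excellent in both metrics at both conditions.
#'
#' @param results data.frame from \code{\link{analyseRobustness}}.
#' @return list with \code{percentages} (data.frame) and \code{robust}
#'   (list of per-kind feature-id sets).
#' @export
summariseFamilies <- function(results) {
  res <- results
  pct <- list()
  for (kind in unique(res$region_kind)) {
    for (cond in unique(res$condition)) {
      sub <- res[res$region_kind == kind & res$condition == cond, ]
      for (metric in c("icc", "sdm")) {
        catv <- sub[[paste0(metric, "_category")]]
        for (fam in c(unique(sub$family), "total")) {
          sel <- if (fam == "total") rep(TRUE, nrow(sub))
                 else sub$family == fam
          cats <- catv[sel]
          n <- sum(!is.na(cats))
          cnt <- vapply(.CATEGORIES, function(cc)
            sum(cats == cc, na.rm = TRUE), numeric(1))
          pct[[length(pct) + 1L]] <- data.frame(
            region_kind = kind, condition = cond, metric = metric,
            family = fam, n_features = sum(sel),
            n_uncategorised = sum(sel) - n,
            t(if (n > 0) 100 * cnt / n else rep(NaN, 4L)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pctDf <- do.call(rbind, pct)
  names(pctDf)[7:10] <- .CATEGORIES
  robust <- list()
  for (kind in unique(res$region_kind)) {
    w <- res[res$region_kind == kind, ]
    byFeat <- split(w, w$feature_id)
    exc <- function(row, cond) {
      r <- row[row$condition == cond, ]
      nrow(r) == 1 && !is.na(r$icc_category) && !is.na(r$sdm_category) &&
        r$icc_category == "excellent" && r$sdm_category == "excellent"
    }
    ge <- function(row, cond) {
      r <- row[row$condition == cond, ]
      nrow(r) == 1 && !is.na(r$icc_category) && !is.na(r$sdm_category) &&
        r$icc_category %in% c("good", "excellent") &&
        r$sdm_category %in% c("good", "excellent")
    }
    robust[[kind]] <- list(
      excellent_s50p = names(byFeat)[vapply(byFeat, exc, logical(1), "S50p")],
      excellent_s25p = names(byFeat)[vapply(byFeat, exc, logical(1), "S25p")],
      good_or_excellent_both = names(byFeat)[
        vapply(byFeat, function(r) ge(r, "S50p") && ge(r, "S25p"),
               logical(1))])
  }
  list(percentages = pctDf, robust = robust)
}
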