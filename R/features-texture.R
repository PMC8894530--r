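## Per-matrix feature formulas for the texture families, plus the averaging
## over aggregation items. Degenerate values are NaN; averaging over items
## skips NaN sub-values and yields NaN only if every item is degenerate.

.GLCM_NAMES <- c(
  "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
  "contrast", "dissimilarity", "inverse_difference",
  "inverse_difference_normalised", "inverse_difference_moment",
  "inverse_difference_moment_normalised", "inverse_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "information_correlation_1",
  "information_correlation_2")

.GLRLM_NAMES <- c(
  "short_runs_emphasis", "long_runs_emphasis", "low_grey_level_run_emphasis",
  "high_grey_level_run_emphasis", "short_run_low_grey_level_emphasis",
  "short_run_high_grey_level_emphasis", "long_run_low_grey_level_emphasis",
  "long_run_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "run_length_non_uniformity",
  "run_length_non_uniformity_normalised", "run_percentage",
  "grey_level_variance", "run_length_variance", "run_entropy")

.GLSZM_NAMES <- c(
  "small_zone_emphasis", "large_zone_emphasis", "low_grey_level_zone_emphasis",
  "high_grey_level_zone_emphasis", "small_zone_low_grey_level_emphasis",
  "small_zone_high_grey_level_emphasis", "large_zone_low_grey_level_emphasis",
  "large_zone_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "zone_size_non_uniformity",
  "zone_size_non_uniformity_normalised", "zone_percentage",
  "grey_level_variance", "zone_size_variance", "zone_size_entropy")

.GLDZM_NAMES <- c(
  "small_distance_emphasis", "large_distance_emphasis",
  "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
  "small_distance_low_grey_level_emphasis",
  "small_distance_high_grey_level_emphasis",
  "large_distance_low_grey_level_emphasis",
  "large_distance_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "zone_distance_non_uniformity",
  "zone_distance_non_uniformity_normalised", "zone_percentage",
  "grey_level_variance", "zone_distance_variance", "zone_distance_entropy")

.NGTDM_NAMES <- c("coarseness", "contrast", "busyness", "complexity",
                  "strength")

.NGLDM_NAMES <- c(
  "low_dependence_emphasis", "high_dependence_emphasis",
  "low_grey_level_count_emphasis", "high_grey_level_count_emphasis",
  "low_dependence_low_grey_level_emphasis",
  "low_dependence_high_grey_level_emphasis",
  "high_dependence_low_grey_level_emphasis",
  "high_dependence_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "dependence_count_non_uniformity",
  "dependence_count_non_uniformity_normalised", "dependence_count_percentage",
  "grey_level_variance", "dependence_count_variance",
  "dependence_count_entropy", "dependence_count_energy")

## 25 GLCM features from one symmetric count matrix.
.glcmFeatureVec <- function(Pc) {
  s <- sum(Pc)
  if (s == 0) return(rep(NaN, 25L))
  P <- Pc / s
  ng <- nrow(P)
  iM <- row(P); jM <- col(P)
  px <- rowSums(P)                       # symmetric: px == py
  mu <- sum(iM * P)                      # grey-level mean of the joint dist
  sigx2 <- sum((seq_len(ng) - mu)^2 * px)
  dIdx <- abs(iM - jM)
  pd <- as.numeric(rowsum(as.numeric(P), as.numeric(dIdx)))        # k = 0..
  dk <- sort(unique(as.numeric(dIdx)))
  sIdx <- iM + jM
  ps <- as.numeric(rowsum(as.numeric(P), as.numeric(sIdx)))
  sk <- sort(unique(as.numeric(sIdx)))
  da <- sum(dk * pd)
  sa <- sum(sk * ps)
  ent0 <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  hxy <- ent0(P)
  hx <- ent0(px)
  pxy <- outer(px, px)
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- ent0(pxy)
  corr <- if (sigx2 == 0) NaN else (sum(iM * jM * P) - mu^2) / sigx2
  out <- c(
    max(P),
    mu,
    sum((iM - mu)^2 * P),
    hxy,
    da,
    sum((dk - da)^2 * pd),
    ent0(pd),
    sa,
    sum((sk - sa)^2 * ps),
    ent0(ps),
    sum(P^2),
    sum(dIdx^2 * P),
    sum(dIdx * P),
    sum(P / (1 + dIdx)),
    sum(P / (1 + dIdx / ng)),
    sum(P / (1 + dIdx^2)),
    sum(P / (1 + (dIdx / ng)^2)),
    {
      off <- dIdx > 0
      if (any(off)) sum(P[off] / dIdx[off]^2) else NaN
    },
    corr,
    sum(iM * jM * P),
    sum((iM + jM - 2 * mu)^2 * P),
    sum((iM + jM - 2 * mu)^3 * P),
    sum((iM + jM - 2 * mu)^4 * P),
    if (hx == 0) NaN else (hxy - hxy1) / hx,
    sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))))
  out
}

## 16 generic row/column emphasis features shared by GLRLM / GLSZM / GLDZM;
## column attribute j is run length, zone size or zone distance.
.rcFeatureVec <- function(M, nVox) {
  Ns <- sum(M)
  if (Ns == 0) return(rep(NaN, 16L))
  P <- M / Ns
  iv <- seq_len(nrow(M)); jv <- seq_len(ncol(M))
  ri <- rowSums(P); cj <- colSums(P)
  mui <- sum(ri * iv); muj <- sum(cj * jv)
  c(sum(cj / jv^2),
    sum(cj * jv^2),
    sum(ri / iv^2),
    sum(ri * iv^2),
    sum(P * outer(1 / iv^2, 1 / jv^2)),
    sum(P * outer(iv^2, 1 / jv^2)),
    sum(P * outer(1 / iv^2, jv^2)),
    sum(P * outer(iv^2, jv^2)),
    sum(rowSums(M)^2) / Ns,
    sum(ri^2),
    sum(colSums(M)^2) / Ns,
    sum(cj^2),
    Ns / nVox,
    sum(ri * (iv - mui)^2),
    sum(cj * (jv - muj)^2),
    -sum(P[P > 0] * log2(P[P > 0])))
}

.ngldmFeatureVec <- function(M, nVox) {
  base <- .rcFeatureVec(M, nVox)
  P <- if (sum(M) > 0) M / sum(M) else M
  c(base, sum(P^2))
}

.ngtdmFeatureVec <- function(item) {
  n <- item$n; s <- item$s; Nv <- item$nVox
  if (Nv == 0) return(rep(NaN, 5L))
  p <- n / Nv
  ii <- seq_along(n)
  pres <- p > 0
  ngp <- sum(pres)
  pi_ <- p[pres]; si <- s[pres]; iv <- ii[pres]
  den <- sum(p * s)
  coarseness <- if (den == 0) 1e6 else 1 / den  # IBSI cap for flat regions
  if (ngp <= 1L) {
    contrast <- 0; busyness <- 0; strength <- 0
  } else {
    contrast <- sum(outer(pi_, pi_) * outer(iv, iv, `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / Nv
    bden <- sum(abs(outer(iv * pi_, iv * pi_, `-`)))
    busyness <- if (bden == 0) 0 else den / bden
    strength <- if (sum(s) == 0) 0 else
      sum(outer(pi_, pi_, `+`) * outer(iv, iv, `-`)^2) / sum(s)
  }
  complexity <- if (ngp <= 1L) 0 else
    sum(abs(outer(iv, iv, `-`)) * outer(pi_ * si, pi_ * si, `+`) /
          outer(pi_, pi_, `+`)) / Nv
  c(coarseness, contrast, busyness, complexity, strength)
}

## Average a per-item feature function over aggregation items.
.avgOverItems <- function(items, fun, nfeat) {
  M <- vapply(items, fun, numeric(nfeat))
  M <- matrix(M, nrow = nfeat)
  apply(M, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NaN else mean(v)
  })
}

#' GLCM features over all six aggregation modes (150)
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @return named numeric(150), ids \code{glcm.<feature>.<aggregation>}.
#' @export
computeGlcmFeatures <- function(dv) {
  out <- numeric(0)
  for (agg in .AGG6) {
    tm <- buildCooccurrence(dv, agg)
    v <- .avgOverItems(tm$items, .glcmFeatureVec, 25L)
    out <- c(out, stats::setNames(v, paste0("glcm.", .GLCM_NAMES, ".", agg)))
  }
  out
}

#' GLRLM features over all six aggregation modes (96)
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @return named numeric(96).
#' @export
computeGlrlmFeatures <- function(dv) {
  out <- numeric(0)
  for (agg in .AGG6) {
    tm <- buildRunLength(dv, agg)
    v <- .avgOverItems(tm$items, function(it) .rcFeatureVec(it$counts, it$nVox),
                       16L)
    out <- c(out, stats::setNames(v, paste0("glrlm.", .GLRLM_NAMES, ".", agg)))
  }
  out
}

#' GLSZM and GLDZM features over the three aggregation modes (48 + 48)
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @return named numeric(96).
#' @export
computeZoneFeatures <- function(dv) {
  out <- numeric(0)
  for (agg in .AGG3) {
    tm <- buildZoneMatrices(dv, agg)
    vS <- .avgOverItems(tm$items, function(it) .rcFeatureVec(it$szm, it$nVox),
                        16L)
    vD <- .avgOverItems(tm$items, function(it) .rcFeatureVec(it$dzm, it$nVox),
                        16L)
    out <- c(out,
             stats::setNames(vS, paste0("glszm.", .GLSZM_NAMES, ".", agg)),
             stats::setNames(vD, paste0("gldzm.", .GLDZM_NAMES, ".", agg)))
  }
  out
}

#' NGTDM and NGLDM features over the three aggregation modes (15 + 51)
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @return named numeric(66).
#' @export
computeNeighbourhoodFeatures <- function(dv) {
  out <- numeric(0)
  for (agg in .AGG3) {
    tmT <- buildNGTDM(dv, agg)
    vT <- .avgOverItems(tmT$items, .ngtdmFeatureVec, 5L)
    tmL <- buildNGLDM(dv, agg)
    vL <- .avgOverItems(tmL$items,
                        function(it) .ngldmFeatureVec(it$counts, it$nVox), 17L)
    out <- c(out,
             stats::setNames(vT, paste0("ngtdm.", .NGTDM_NAMES, ".", agg)),
             stats::setNames(vL, paste0("ngldm.", .NGLDM_NAMES, ".", agg)))
  }
  out
}
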