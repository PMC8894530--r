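# Feature-family values: hand oracles, closed forms, catalogue arithmetic,
# determinism and symmetry invariances.

test_that("intensity statistics match hand arithmetic on {1,2,3,4}", {
  f <- makeSuvVoi(array(c(1, 2, 3, 4), c(4, 1, 1)))
  v <- computeIntensityStatistics(f$scan, f$voi)
  expect_equal(unname(v["stat.mean"]), 2.5)
  expect_equal(unname(v["stat.variance"]), 1.25)  # population convention
  expect_equal(unname(v["stat.energy"]), 1 + 4 + 9 + 16)
  expect_equal(unname(v["stat.root_mean_square"]), sqrt(30 / 4))
  expect_equal(unname(v["stat.range"]), 3)
  expect_equal(unname(v["stat.median_absolute_deviation"]), 1)
  # RMS^2 = variance + mean^2 on arbitrary data
  g <- makeSuvVoi(array(runif(27, 0, 5), c(3, 3, 3)))
  w <- computeIntensityStatistics(g$scan, g$voi)
  expect_equal(unname(w["stat.root_mean_square"]^2),
               unname(w["stat.variance"] + w["stat.mean"]^2))
})

test_that("constant region yields degenerate NaN flags, not zeros", {
  f <- makeSuvVoi(array(5, c(3, 3, 3)))
  v <- computeIntensityStatistics(f$scan, f$voi)
  expect_equal(unname(v["stat.variance"]), 0)
  expect_true(is.nan(v["stat.skewness"]))
  expect_true(is.nan(v["stat.kurtosis"]))
})

test_that("histogram features: entropy/uniformity closed forms", {
  # single level
  v1 <- computeIntensityHistogram(makeDV(array(3L, c(3, 3, 1))))
  expect_equal(unname(v1["ih.entropy"]), 0)
  expect_equal(unname(v1["ih.uniformity"]), 1)
  # uniform over Ng levels -> entropy log2 Ng
  lv <- array(rep(1:4, each = 4), c(4, 4, 1))
  vu <- computeIntensityHistogram(makeDV(lv))
  expect_equal(unname(vu["ih.entropy"]), log2(4))
  expect_equal(unname(vu["ih.uniformity"]), 4 * (1 / 4)^2)
  # two-level (3/4, 1/4) -> uniformity 0.625
  lv2 <- array(c(rep(1L, 6), rep(2L, 2)), c(8, 1, 1))
  v2 <- computeIntensityHistogram(makeDV(lv2))
  expect_equal(unname(v2["ih.uniformity"]), 0.625)
  expect_equal(unname(v2["ih.mode"]), 1)
  expect_equal(unname(v2["ih.energy"]), 6 * 1 + 2 * 4)
})

test_that("IVH features: constant and linear-ramp closed forms", {
  cst <- makeSuvVoi(array(4, c(3, 3, 1)))
  v <- computeIVH(cst$scan, cst$voi)
  expect_equal(unname(v["ivh.i10"]), unname(v["ivh.i90"]))
  expect_equal(unname(v["ivh.i10_minus_i90"]), 0)
  expect_true(all(v[c("ivh.v10", "ivh.v90")] >= 0 &
                    v[c("ivh.v10", "ivh.v90")] <= 1))
  # ramp 1..100: V(g) = fraction >= 1 + g*99; I_p = (100 - ceil(p*100)) + 1
  r <- makeSuvVoi(array(as.numeric(1:100), c(100, 1, 1)))
  vr <- computeIVH(r$scan, r$voi)
  expect_equal(unname(vr["ivh.v10"]), mean(1:100 >= 1 + 0.1 * 99))
  expect_equal(unname(vr["ivh.v90"]), mean(1:100 >= 1 + 0.9 * 99))
  expect_equal(unname(vr["ivh.i10"]), 91)  # 10th largest of 1..100
  expect_equal(unname(vr["ivh.i90"]), 11)
  expect_equal(unname(vr["ivh.i10_minus_i90"]), 80)
})

test_that("local intensity peaks: constant VOI and single hot voxel", {
  cst <- makeSuvVoi(array(5, c(9, 9, 9)))
  v <- computeLocalIntensity(cst$scan, cst$voi)
  expect_equal(unname(v["loc.peak_local"]), 5)
  expect_equal(unname(v["loc.peak_global"]), 5)
  # single hot voxel in zero background: peak = hot / (sphere voxel count)
  a <- array(0, c(15, 15, 15)); a[8, 8, 8] <- 100
  f <- makeSuvVoi(a + 0)  # mask everywhere
  f$voi <- voiMask(array(TRUE, dim(a)))
  v2 <- computeLocalIntensity(scanVolume(a, spacing = 2, unit = "SUV"),
                              f$voi)
  r <- (3 / (4 * pi) * 1000)^(1 / 3)
  offs <- expand.grid(-3:3, -3:3, -3:3)
  nSphere <- sum(sqrt(rowSums((offs * 2)^2)) <= r + 1e-9)
  expect_equal(unname(v2["loc.peak_local"]), 100 / nSphere)
  expect_equal(unname(v2["loc.peak_global"]), 100 / nSphere)
})

test_that("GLCM features match direct formula evaluation on a toy grid", {
  withr::local_seed(7)
  lv <- array(sample.int(3, 16, replace = TRUE), c(4, 4, 1))
  dv <- makeDV(lv)
  tm <- buildCooccurrence(dv, "25d_mrg")
  Pc <- tm$items[[1]]
  got <- zirconomics:::.glcmFeatureVec(Pc)
  names(got) <- zirconomics:::.GLCM_NAMES
  # independent evaluation from first principles on the oracle matrix
  P <- Pc / sum(Pc)
  ng <- nrow(P)
  ii <- row(P); jj <- col(P)
  mu <- sum(ii * P)
  px <- rowSums(P)
  expect_equal(unname(got["joint_maximum"]), max(P))
  expect_equal(unname(got["joint_average"]), mu)
  expect_equal(unname(got["joint_entropy"]),
               -sum(P[P > 0] * log2(P[P > 0])))
  expect_equal(unname(got["angular_second_moment"]), sum(P^2))
  expect_equal(unname(got["contrast"]), sum((ii - jj)^2 * P))
  expect_equal(unname(got["dissimilarity"]), sum(abs(ii - jj) * P))
  expect_equal(unname(got["inverse_difference"]),
               sum(P / (1 + abs(ii - jj))))
  expect_equal(unname(got["inverse_variance"]),
               sum((P / (ii - jj)^2)[ii != jj]))
  expect_equal(unname(got["autocorrelation"]), sum(ii * jj * P))
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  expect_equal(unname(got["correlation"]),
               (sum(ii * jj * P) - mu^2) / sig2)
  expect_equal(unname(got["cluster_shade"]), sum((ii + jj - 2 * mu)^3 * P))
  da <- sum(abs(ii - jj) * P)
  expect_equal(unname(got["difference_average"]), da)
  expect_equal(unname(got["difference_variance"]),
               sum((abs(ii - jj) - da)^2 * P))
  sa <- sum((ii + jj) * P)
  expect_equal(unname(got["sum_average"]), sa)
  expect_equal(unname(got["sum_variance"]), sum(((ii + jj) - sa)^2 * P))
  # bounds on random VOIs
  expect_gte(unname(got["contrast"]), 0)
  expect_true(abs(got["correlation"]) <= 1 + 1e-12)
})

test_that("run/zone emphasis features match direct formulas on a toy matrix", {
  M <- matrix(c(3, 1, 0, 2,
                0, 2, 1, 0,
                1, 0, 0, 1), nrow = 3, byrow = TRUE)
  nVox <- sum(M %*% 1:4)
  got <- zirconomics:::.rcFeatureVec(M, nVox)
  names(got) <- zirconomics:::.GLRLM_NAMES
  Ns <- sum(M); P <- M / Ns
  iv <- 1:3; jv <- 1:4
  expect_equal(unname(got["short_runs_emphasis"]), sum(colSums(P) / jv^2))
  expect_equal(unname(got["long_runs_emphasis"]), sum(colSums(P) * jv^2))
  expect_equal(unname(got["low_grey_level_run_emphasis"]),
               sum(rowSums(P) / iv^2))
  expect_equal(unname(got["grey_level_non_uniformity"]),
               sum(rowSums(M)^2) / Ns)
  expect_equal(unname(got["run_length_non_uniformity_normalised"]),
               sum(colSums(P)^2))
  expect_equal(unname(got["run_percentage"]), Ns / nVox)
  expect_equal(unname(got["run_entropy"]), -sum(P[P > 0] * log2(P[P > 0])))
  mui <- sum(rowSums(P) * iv)
  expect_equal(unname(got["grey_level_variance"]),
               sum(rowSums(P) * (iv - mui)^2))
})

test_that("catalogue has 458 features with the family inventory", {
  cat_df <- featureCatalogue()
  expect_identical(nrow(cat_df), 458L)
  counts <- table(cat_df$family)
  expect_identical(as.integer(counts[c("loc", "stat", "ih", "ivh", "glcm",
                                       "glrlm", "glszm", "gldzm", "ngtdm",
                                       "ngldm")]),
                   c(2L, 18L, 24L, 6L, 150L, 96L, 48L, 48L, 15L, 51L))
  expect_false(anyDuplicated(cat_df$id) > 0)
})

test_that("extraction is complete, deterministic and degenerate-safe", {
  sp <- tinySpec()
  ds <- buildDataset(list(sp), seed = 3)
  p <- patients(ds)[[1]]
  fv1 <- extractAllFeatures(p$scans$full, p$masks[[1]], p$meta)
  fv2 <- extractAllFeatures(p$scans$full, p$masks[[1]], p$meta)
  expect_identical(fv1, fv2)
  expect_identical(names(fv1), featureCatalogue()$id)
  # one grey level: entropies 0, uniformity/energy-type features 1
  a <- array(0, c(12, 12, 12)); a[4:9, 4:9, 4:9] <- 1.1
  m <- array(FALSE, dim(a)); m[4:9, 4:9, 4:9] <- TRUE
  sv <- scanVolume(a, spacing = 2, unit = "SUV")
  fv <- extractAllFeatures(sv, voiMask(m))
  expect_equal(unname(fv["ih.entropy"]), 0)
  expect_equal(unname(fv["ih.uniformity"]), 1)
  expect_equal(unname(fv["glcm.joint_entropy.3d_mrg"]), 0)
  expect_equal(unname(fv["glcm.angular_second_moment.3d_mrg"]), 1)
  expect_equal(unname(fv["glcm.joint_maximum.2d_avg"]), 1)
  expect_true(is.nan(fv["stat.skewness"]))
})

test_that("merged-3D texture features are translation and rotation invariant", {
  withr::local_seed(55)
  base <- array(sample.int(4, 6^3, replace = TRUE), c(6, 6, 6))
  pad <- function(arr, d0) {
    a <- array(0, c(14, 14, 14))
    a[d0[1] + 1:6, d0[2] + 1:6, d0[3] + 1:6] <- arr
    m <- array(FALSE, c(14, 14, 14))
    m[d0[1] + 1:6, d0[2] + 1:6, d0[3] + 1:6] <- TRUE
    sv <- scanVolume(a * 0.25, spacing = 2, unit = "SUV")
    extractAllFeatures(sv, voiMask(m))
  }
  sel <- grep("(3d_mrg|3d_avg|\\.3d$)", featureCatalogue()$id, value = TRUE)
  f0 <- pad(base, c(2, 2, 2))
  fT <- pad(base, c(5, 3, 4))                     # translation
  rot <- aperm(base[, 6:1, ], c(2, 1, 3))         # 90 deg about z
  fR <- pad(rot, c(2, 2, 2))
  expect_equal(f0[sel], fT[sel], tolerance = 1e-10)
  expect_equal(f0[sel], fR[sel], tolerance = 1e-10)
})
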