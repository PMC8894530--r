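# ICC, SDM, subsampling, categorisation, Fisher comparison, family summary.

test_that("ICC matches the two-way ANOVA oracle on random matrices", {
  withr::local_seed(11)
  for (i in 1:50) {
    n <- sample(4:10, 1); k <- sample(c(2, 4), 1)
    Y <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n, sd = 2)  # row effects
    expect_equal(iccAbsoluteAgreement(Y), oracleIcc(Y), tolerance = 1e-10)
  }
})

test_that("ICC trivial and degenerate cases", {
  Y <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(iccAbsoluteAgreement(Y), 1)
  expect_true(is.nan(iccAbsoluteAgreement(matrix(5, 4, 2))))
  expect_error(iccAbsoluteAgreement(matrix(1, 1, 2)), "at least 2")
  # vectorised path agrees with the scalar path
  withr::local_seed(12)
  Y3 <- array(rnorm(6 * 4 * 5), c(6, 4, 5))
  v <- zirconomics:::.iccAll(Y3)
  for (f in 1:5)
    expect_equal(v[f], iccAbsoluteAgreement(Y3[, , f]), tolerance = 1e-12)
})

test_that("ICC tends to 1 as replicate noise vanishes", {
  withr::local_seed(13)
  subj <- rnorm(10, sd = 3)
  for (s in c(1, 0.1, 0.001)) {
    Y <- subj + matrix(rnorm(20, sd = s), 10, 2)
    if (s == 0.001) expect_gt(iccAbsoluteAgreement(Y), 0.999)
  }
})

test_that("SDM matches the direct formula, fixing the variance convention", {
  f <- c(1, 2, 3)
  R <- cbind(c(1.1, 2.1, 3.1))
  # sample variance of f is 1; mean squared distance is 0.01
  expect_equal(sdm(f, R), 1 / (0.01 + 1))
  # all columns identical to f -> 1
  expect_equal(sdm(f, cbind(f, f)), 1)
  # enormous distances -> 0
  expect_lt(sdm(f, cbind(f + 1e6)), 1e-9)
  # average over replicate columns
  expect_equal(sdm(f, cbind(f, f + 1)),
               mean(c(1, 1 / (mean((1)^2 * c(1, 1, 1)) + 1))))
})

test_that("SDM stays in [0,1] and decreases with every distance term", {
  withr::local_seed(21)
  for (i in 1:25) {
    n <- sample(3:8, 1); m <- sample(c(2, 4), 1)
    f <- rnorm(n, sd = 2)
    R <- f + matrix(rnorm(n * m), n, m)
    v <- sdm(f, R)
    expect_true(v >= 0 && v <= 1)
    # inflating one replicate's distance can only lower the SDM
    R2 <- R; R2[, 1] <- R2[, 1] + 5
    expect_lte(sdm(f, R2), v + 1e-12)
  }
  # vectorised path agrees
  Fm <- matrix(rnorm(12), 6, 2)
  R <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  v <- zirconomics:::.sdmAll(Fm, R)
  for (j in 1:2) expect_equal(v[j], sdm(Fm[, j], R[, , j]))
})

test_that("subsampling respects the per-patient cap and iteration count", {
  regions <- data.frame(
    region_id = c(paste0("A", 1:2), paste0("B", 1:5)),
    patient_id = c(rep("A", 2), rep("B", 5)))
  subsets <- subsampleIterations(regions, subsampleScheme(100, 3, seed = 9))
  expect_length(subsets, 100)
  for (s in subsets) {
    expect_setequal(intersect(s, c("A1", "A2")), c("A1", "A2"))  # <=3: all
    expect_identical(sum(startsWith(s, "B")), 3L)                 # capped
    expect_false(anyDuplicated(s) > 0)                            # no repl.
  }
  # sampling varies across iterations but is seed-deterministic
  subsets2 <- subsampleIterations(regions, subsampleScheme(100, 3, seed = 9))
  expect_identical(subsets, subsets2)
  expect_gt(length(unique(vapply(subsets, function(s)
    paste(sort(s), collapse = ","), character(1)))), 1)
})

test_that("category cut-offs sit exactly at 0.5, 0.75 and 0.9", {
  x <- c(0.9, 0.75, 0.5, -0.2, 0.89999, 0.749, 0.49, 1, 0, NaN)
  got <- as.character(categoriseMetric(x))
  expect_identical(got,
                   c("excellent", "good", "moderate", "poor", "good",
                     "moderate", "poor", "excellent", "poor", NA))
})

test_that("noiseless replicates summarise to ICC = SDM = 1, excellent", {
  withr::local_seed(31)
  f <- rnorm(8, 5, 2)
  mm <- measurementMatrix(cbind(f, f), fullCount = f,
                          patientId = rep(c("A", "B"), each = 4),
                          featureId = "toy")
  res <- summariseFeature(mm, subsampleScheme(20, 3, seed = 1))
  expect_equal(res$icc_mean, 1)
  expect_equal(res$sdm_mean, 1)
  expect_identical(res$icc_category, "excellent")
  expect_identical(res$sdm_category, "excellent")
})

test_that("all patients under the cap collapses iteration spread to zero", {
  withr::local_seed(32)
  f <- rnorm(6, 5, 2)
  R <- f + matrix(rnorm(12, sd = 0.3), 6, 2)
  mm <- measurementMatrix(R, fullCount = f,
                          patientId = rep(c("A", "B", "C"), each = 2))
  res <- summariseFeature(mm, subsampleScheme(50, 3, seed = 2))
  expect_equal(res$icc_sd, 0)
  expect_equal(res$sdm_sd, 0)
  expect_equal(res$icc_lo, res$icc_hi)
})

test_that("a heavily noised feature ranks below a clean one in SDM", {
  withr::local_seed(33)
  f <- rnorm(9, 10, 3)
  clean <- f + matrix(rnorm(18, sd = 0.1), 9, 2)
  noisy <- f + matrix(rnorm(18, sd = 6), 9, 2)
  sClean <- summariseFeature(
    measurementMatrix(clean, f, rep(c("A", "B", "C"), each = 3)),
    subsampleScheme(50, 3, seed = 3))
  sNoisy <- summariseFeature(
    measurementMatrix(noisy, f, rep(c("A", "B", "C"), each = 3)),
    subsampleScheme(50, 3, seed = 3))
  expect_lt(sNoisy$sdm_mean, sClean$sdm_mean)
  expect_lt(sNoisy$icc_mean, sClean$icc_mean)
})

test_that("Fisher comparison: proportional, enumeration oracle, symmetry", {
  expect_equal(compareCategoryDistributions(c(10, 10, 10, 10),
                                            c(20, 20, 20, 20))$p.value, 1)
  tab <- cbind(c(5, 0, 0, 0), c(0, 5, 0, 0))
  got <- compareCategoryDistributions(tab[, 1], tab[, 2])
  expect_equal(got$p.value, oracleFisherRx2(tab[rowSums(tab) > 0, ]),
               tolerance = 1e-10)
  a <- c(7, 3, 2, 1); b <- c(2, 4, 4, 5)
  expect_equal(compareCategoryDistributions(a, b)$p.value,
               compareCategoryDistributions(b, a)$p.value)
  expect_equal(compareCategoryDistributions(a, b)$p.value,
               oracleFisherRx2(cbind(a, b)), tolerance = 1e-8)
  expect_error(compareCategoryDistributions(rep(0, 4), rep(0, 4)),
               "all-zero")
  # Monte-Carlo path triggers above the threshold and is reproducible
  big <- compareCategoryDistributions(c(3000, 10, 5, 2), c(10, 3000, 5, 2),
                                      mcThreshold = 100, B = 2000, seed = 4)
  expect_identical(big$method, "monte-carlo")
  expect_lt(big$p.value, 0.01)
})

test_that("family summary percentages are conserved and sets intersect", {
  res <- data.frame(
    feature_id = rep(paste0("f", 1:4), 2),
    family = rep(c("glcm", "glcm", "stat", "stat"), 2),
    region_kind = "tumour",
    condition = rep(c("S50p", "S25p"), each = 4),
    icc_category = c("excellent", "good", "excellent", NA,
                     "good", "moderate", "excellent", NA),
    sdm_category = c("excellent", "excellent", "good", "poor",
                     "good", "poor", "excellent", "poor"),
    stringsAsFactors = FALSE)
  fam <- summariseFamilies(res)
  pct <- fam$percentages
  tot <- pct[pct$family == "total" & pct$metric == "icc" &
               pct$condition == "S50p", ]
  expect_equal(tot$poor + tot$moderate + tot$good + tot$excellent, 100)
  expect_equal(tot$n_uncategorised, 1)
  # set algebra: excellent-in-both at S50p
  exc <- fam$robust$tumour$excellent_s50p
  expect_setequal(exc, "f1")
  ge <- fam$robust$tumour$good_or_excellent_both
  expect_setequal(ge, c("f1", "f3"))  # good-or-excellent in both conditions
  # all excellent -> every family row (0,0,0,100)
  resx <- res
  resx$icc_category <- "excellent"; resx$sdm_category <- "excellent"
  px <- summariseFamilies(resx)$percentages
  expect_true(all(px$excellent == 100))
})

test_that("summariseFeature agrees with the dataset-level engine", {
  withr::local_seed(41)
  # construct a small SummarizedExperiment by hand with 2 features
  regions <- expand.grid(region = paste0("r", 1:6),
                         rep = c("full", "s50p_1", "s50p_2"))
  f1full <- rnorm(6, 10, 2); f2full <- rnorm(6, 3, 1)
  noise <- function(sd) rnorm(6, 0, sd)
  m <- rbind(
    c(f1full, f1full + noise(0.2), f1full + noise(0.2)),
    c(f2full, f2full + noise(0.8), f2full + noise(0.8)))
  cd <- data.frame(
    patient_id = rep(rep(c("A", "B", "C"), each = 2), 3),
    region_id = rep(paste0("r", 1:6), 3),
    region_kind = "tumour",
    condition = rep(c("full", "S50p", "S50p"), each = 6),
    replicate = rep(c("full", "s50p_1", "s50p_2"), each = 6))
  rownames(cd) <- paste(cd$region_id, cd$replicate, sep = "/")
  cat2 <- featureCatalogue()[1:2, ]
  rownames(m) <- cat2$id
  colnames(m) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m),
    rowData = S4Vectors::DataFrame(cat2, row.names = cat2$id),
    colData = S4Vectors::DataFrame(cd))
  scheme <- subsampleScheme(30, 2, seed = 5)
  res <- analyseRobustness(se, scheme, conditions = "S50p")
  mm <- measurementMatrix(cbind(m[1, 7:12], m[1, 13:18]),
                          fullCount = m[1, 1:6],
                          patientId = cd$patient_id[1:6],
                          featureId = cat2$id[1])
  single <- summariseFeature(mm, scheme)
  expect_equal(res$icc_mean[1], single$icc_mean)
  expect_equal(res$sdm_mean[1], single$sdm_mean)
  expect_equal(res$icc_sd[1], single$icc_sd)
  expect_equal(res$sdm_lo[1], single$sdm_lo)
})
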