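# Texture-matrix builders against exhaustive brute-force oracles and
# constructed cases.

test_that("3-D GLCM equals exhaustive pair enumeration on random grids", {
  withr::local_seed(101)
  dirs <- oracleDirs3d()
  for (i in 1:8) {
    lv <- randomLevelGrid()
    ng <- max(lv, na.rm = TRUE)
    dv <- makeDV(lv)
    tm <- buildCooccurrence(dv, "3d_avg")
    for (r in seq_along(dirs))
      expect_equal(tm$items[[r]][seq_len(ng), seq_len(ng)],
                   oracleGlcm(lv, dirs[[r]], ng))
    merged <- buildCooccurrence(dv, "3d_mrg")$items[[1]]
    expect_equal(merged[seq_len(ng), seq_len(ng)],
                 Reduce(`+`, lapply(dirs, oracleGlcm, lv = lv, ng = ng)))
  }
})

test_that("GLCM constructed cases: constant slice and checkerboard", {
  lv <- array(1L, c(2, 2, 1))
  tm <- buildCooccurrence(makeDV(lv), "2d_smrg")
  M <- tm$items[[1]]
  # 2 + 2 axis pairs + 1 + 1 diagonal pairs, each counted in both orders
  expect_equal(sum(M), 12)
  expect_equal(M[1, 1], sum(M))          # all mass at (1,1)
  # checkerboard: axis-aligned directions have zero diagonal mass
  cb <- array(NA_integer_, c(4, 4, 1))
  cb[] <- (outer(1:4, 1:4, `+`) %% 2) + 1L
  dirs2d <- list(c(1, -1), c(1, 0), c(1, 1), c(0, 1))  # package order
  horiz <- which(vapply(dirs2d, function(o) all(o == c(1, 0)), logical(1)))
  d1 <- buildCooccurrence(makeDV(cb), "2d_avg")$items[[horiz]]
  expect_equal(sum(diag(d1)), 0)
  expect_error(buildCooccurrence(makeDV(array(1L, c(1, 1, 1)))), "empty")
})

test_that("run-length matrices equal brute-force run walking", {
  withr::local_seed(202)
  dirs <- oracleDirs3d()
  for (i in 1:8) {
    lv <- randomLevelGrid()
    ng <- max(lv, na.rm = TRUE)
    tm <- buildRunLength(makeDV(lv), "3d_avg")
    for (r in seq_along(dirs)) {
      got <- tm$items[[r]]$counts
      ora <- oracleRuns(lv, dirs[[r]], ng)
      nc <- max(ncol(got), ncol(ora))
      pad <- function(m) cbind(m, matrix(0, nrow(m), nc - ncol(m)))
      expect_equal(pad(got[seq_len(ng), , drop = FALSE]), pad(ora))
    }
  }
  # constant line: single run of length N along the x direction
  xdir <- which(vapply(dirs, function(o) all(o == c(1, 0, 0)), logical(1)))
  line <- array(1L, c(5, 1, 1))
  got <- buildRunLength(makeDV(line), "3d_avg")$items[[xdir]]$counts
  expect_equal(got[1, ], c(0, 0, 0, 0, 1))
  # alternating line: all runs length 1
  alt <- array(c(1L, 2L, 1L, 2L, 1L), c(5, 1, 1))
  got <- buildRunLength(makeDV(alt), "3d_avg")$items[[xdir]]$counts
  expect_true(all(got[, -1] == 0) && sum(got[, 1]) == 5)
})

test_that("zone matrices equal flood-fill + exhaustive distance oracles", {
  withr::local_seed(303)
  for (i in 1:6) {
    lv <- randomLevelGrid(dmax = c(5, 5, 3))
    ng <- max(lv, na.rm = TRUE)
    zm <- buildZoneMatrices(makeDV(lv), "3d")$items[[1]]
    zo <- oracleZones(lv, oracleNb26())
    # GLSZM: zone (level, size) multiset identical
    sizes <- vapply(zo, function(z) length(z$members), numeric(1))
    levs <- vapply(zo, function(z) z$level, numeric(1))
    M <- matrix(0, ng, max(sizes))
    for (j in seq_along(zo)) M[levs[j], sizes[j]] <- M[levs[j], sizes[j]] + 1
    expect_equal(zm$szm[seq_len(ng), seq_len(max(sizes)), drop = FALSE], M)
    # GLDZM: per-zone min of brute-force edge distances
    mask <- !is.na(lv)
    zd <- vapply(zo, function(z)
      min(vapply(z$members, function(p) oracleEdgeDist(mask, p),
                 numeric(1))), numeric(1))
    D <- matrix(0, ng, max(zd))
    for (j in seq_along(zo)) D[levs[j], zd[j]] <- D[levs[j], zd[j]] + 1
    expect_equal(zm$dzm[seq_len(ng), seq_len(max(zd)), drop = FALSE], D)
  }
})

test_that("2-D zones use 8-connectivity and in-plane distances", {
  withr::local_seed(304)
  lv <- randomLevelGrid(dmax = c(6, 6, 1))
  ng <- max(lv, na.rm = TRUE)
  zm <- buildZoneMatrices(makeDV(lv), "2d")$items[[1]]
  zo <- oracleZones(lv, oracleNb8())
  sizes <- vapply(zo, function(z) length(z$members), numeric(1))
  expect_equal(sum(zm$szm), length(zo))
  expect_equal(sum(zm$szm * col(zm$szm)), sum(sizes))
  mask <- !is.na(lv)
  zd <- vapply(zo, function(z)
    min(vapply(z$members, function(p) oracleEdgeDist(mask, p, inPlane = TRUE),
               numeric(1))), numeric(1))
  expect_equal(sum(zm$dzm * col(zm$dzm)),
               sum(zd))
})

test_that("zone constructed cases: one zone per constant VOI, additive blobs", {
  lv <- array(1L, c(3, 3, 2))
  zm <- buildZoneMatrices(makeDV(lv), "3d")$items[[1]]
  expect_equal(sum(zm$szm), 1)
  expect_equal(zm$szm[1, 18], 1)
  # two disjoint same-level blobs -> two zones with additive sizes
  lv2 <- array(NA_integer_, c(7, 3, 1))
  lv2[1:2, , 1] <- 1L; lv2[6:7, 1:2, 1] <- 1L
  zm2 <- buildZoneMatrices(makeDV(lv2), "3d")$items[[1]]
  expect_equal(sum(zm2$szm), 2)
  expect_equal(sum(zm2$szm * col(zm2$szm)), sum(!is.na(lv2)))
})

test_that("NGTDM and NGLDM equal exhaustive neighbourhood scans", {
  withr::local_seed(404)
  for (i in 1:6) {
    lv <- randomLevelGrid()
    ng <- max(lv, na.rm = TRUE)
    gt <- buildNGTDM(makeDV(lv), "3d")$items[[1]]
    or <- oracleNgtdm(lv, oracleNb26(), ng)
    expect_equal(gt$n[seq_len(ng)], or$n)
    expect_equal(gt$s[seq_len(ng)], or$s, tolerance = 1e-12)
    expect_equal(gt$nVox, or$nVox)
    gl <- buildNGLDM(makeDV(lv), "3d")$items[[1]]
    om <- oracleNgldm(lv, oracleNb26(), ng)
    expect_equal(gl$counts[seq_len(ng), seq_len(ncol(om)), drop = FALSE], om)
  }
  # conservation: sum n_i equals valid voxels; s_i >= 0
  lv <- randomLevelGrid()
  gt <- buildNGTDM(makeDV(lv), "3d")$items[[1]]
  expect_true(all(gt$s >= 0))
  expect_equal(sum(gt$n), gt$nVox)
})

test_that("constant VOI neighbourhood families behave degenerately", {
  lv <- array(2L, c(4, 4, 4))
  dv <- makeDV(lv)
  gt <- buildNGTDM(dv, "3d")$items[[1]]
  expect_equal(sum(gt$s), 0)  # no grey-tone differences
  gl <- buildNGLDM(dv, "3d")$items[[1]]
  # interior voxels: dependence count = full 26-neighbourhood + centre
  expect_equal(gl$counts[2, 27], 2^3)  # the 8 interior voxels of a 4^3 cube
})
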