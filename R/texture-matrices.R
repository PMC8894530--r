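## Texture-matrix builders operating on a DiscretisedVoi (grey levels 1..Ng
## inside the mask, NA outside). Neighbourhoods are Chebyshev distance 1:
## 26-connected in 3-D, 8-connected in 2-D; slices are taken along the third
## axis. Aggregation labels follow the IBSI scheme: six modes for GLCM/GLRLM
## (2d_avg, 2d_smrg, 25d_dmrg, 25d_mrg, 3d_avg, 3d_mrg) and three (2d, 25d,
## 3d) for the zone and neighbourhood families.

.halfOffsets <- function(offs) {
  keep <- apply(offs, 1L, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1L]] > 0
  })
  offs[keep, , drop = FALSE]
}

.allOffsets3d <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})
.allOffsets2d <- .allOffsets3d[.allOffsets3d[, 3L] == 0, , drop = FALSE]
.DIRS3D <- .halfOffsets(.allOffsets3d)  # 13 unique 3-D directions
.DIRS2D <- .halfOffsets(.allOffsets2d)  # 4 unique in-plane directions

.AGG6 <- c("2d_avg", "2d_smrg", "25d_dmrg", "25d_mrg", "3d_avg", "3d_mrg")
.AGG3 <- c("2d", "25d", "3d")

.sliceIdx <- function(lv) which(apply(!is.na(lv), 3L, any))

.slice <- function(lv, k) lv[, , k, drop = FALSE]

## ---- GLCM ----

.glcmPairCounts <- function(lv, off, ng) {
  b <- .shiftArr(lv, off)
  ok <- !is.na(lv) & !is.na(b)
  if (!any(ok)) return(matrix(0, ng, ng))
  i <- lv[ok]; j <- b[ok]
  m <- matrix(tabulate((j - 1L) * ng + i, nbins = ng * ng), ng, ng)
  m + t(m)  # symmetric by construction
}

.sumMats <- function(lst) Reduce(`+`, lst)

#' Build grey-level co-occurrence matrices
#'
#' Symmetric GLCMs at Chebyshev distance 1 over the 13 unique 3-D directions
#' (3-D modes) or 4 in-plane directions per slice (2-D modes), under one of
#' the six IBSI aggregation modes.
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @param aggregation one of \code{"2d_avg"}, \code{"2d_smrg"},
#'   \code{"25d_dmrg"}, \code{"25d_mrg"}, \code{"3d_avg"}, \code{"3d_mrg"}.
#' @return list with \code{family}, \code{aggregation} and \code{items}, a
#'   list of count matrices (several for averaged modes, one for merged).
#' @export
buildCooccurrence <- function(dv, aggregation = "3d_mrg") {
  aggregation <- match.arg(aggregation, .AGG6)
  lv <- dv@levels; ng <- dv@ng
  if (startsWith(aggregation, "3d")) {
    per <- lapply(seq_len(nrow(.DIRS3D)),
                  function(r) .glcmPairCounts(lv, .DIRS3D[r, ], ng))
    items <- if (aggregation == "3d_avg") per else list(.sumMats(per))
  } else {
    ks <- .sliceIdx(lv)
    bySlice <- lapply(ks, function(k) {
      sl <- .slice(lv, k)
      lapply(seq_len(nrow(.DIRS2D)),
             function(r) .glcmPairCounts(sl, .DIRS2D[r, ], ng))
    })
    items <- switch(aggregation,
      "2d_avg"   = unlist(bySlice, recursive = FALSE),
      "2d_smrg"  = lapply(bySlice, .sumMats),
      "25d_dmrg" = lapply(seq_len(nrow(.DIRS2D)), function(r)
                     .sumMats(lapply(bySlice, `[[`, r))),
      "25d_mrg"  = list(.sumMats(lapply(bySlice, .sumMats))))
  }
  if (sum(vapply(items, sum, numeric(1))) == 0)
    stop("empty co-occurrence matrix: VOI has no neighbouring voxel pairs")
  list(family = "glcm", aggregation = aggregation, items = items)
}

## ---- GLRLM ----

## Run-length counts along one direction by iterative forward propagation:
## L[v] converges to the remaining run length starting at v.
.runCounts <- function(lv, off, ng) {
  same <- {
    nxt <- .shiftArr(lv, off)
    !is.na(lv) & !is.na(nxt) & lv == nxt
  }
  L <- array(NA_real_, dim(lv))
  L[!is.na(lv)] <- 1
  if (any(same)) {
    repeat {
      Ln <- .shiftArr(L, off)
      Lnew <- L
      Lnew[same] <- 1 + Ln[same]
      if (identical(Lnew, L)) break
      L <- Lnew
    }
  }
  prev <- .shiftArr(lv, -off)
  isStart <- !is.na(lv) & (is.na(prev) | prev != lv)
  lev <- lv[isStart]; len <- L[isStart]
  if (length(lev) == 0L) return(matrix(0, ng, 1L))
  maxl <- max(len)
  matrix(tabulate((len - 1) * ng + lev, nbins = ng * maxl), ng, maxl)
}

.padCols <- function(m, nc) {
  if (ncol(m) >= nc) return(m)
  cbind(m, matrix(0, nrow(m), nc - ncol(m)))
}

.sumMatsPad <- function(lst) {
  nc <- max(vapply(lst, ncol, integer(1)))
  Reduce(`+`, lapply(lst, .padCols, nc = nc))
}

#' Build grey-level run-length matrices
#'
#' @inheritParams buildCooccurrence
#' @return list with \code{family}, \code{aggregation} and \code{items}; each
#'   item carries \code{counts} and the voxel total \code{nVox} used for run
#'   percentage (summed when matrices are merged).
#' @export
buildRunLength <- function(dv, aggregation = "3d_mrg") {
  aggregation <- match.arg(aggregation, .AGG6)
  lv <- dv@levels; ng <- dv@ng
  item <- function(counts, nVox) list(counts = counts, nVox = nVox)
  if (startsWith(aggregation, "3d")) {
    nv <- sum(!is.na(lv))
    per <- lapply(seq_len(nrow(.DIRS3D)),
                  function(r) item(.runCounts(lv, .DIRS3D[r, ], ng), nv))
    items <- if (aggregation == "3d_avg") per
             else list(item(.sumMatsPad(lapply(per, `[[`, "counts")),
                            nv * nrow(.DIRS3D)))
  } else {
    ks <- .sliceIdx(lv)
    bySlice <- lapply(ks, function(k) {
      sl <- .slice(lv, k)
      nv <- sum(!is.na(sl))
      lapply(seq_len(nrow(.DIRS2D)),
             function(r) item(.runCounts(sl, .DIRS2D[r, ], ng), nv))
    })
    mergeItems <- function(its) item(.sumMatsPad(lapply(its, `[[`, "counts")),
                                     sum(vapply(its, `[[`, numeric(1), "nVox")))
    items <- switch(aggregation,
      "2d_avg"   = unlist(bySlice, recursive = FALSE),
      "2d_smrg"  = lapply(bySlice, mergeItems),
      "25d_dmrg" = lapply(seq_len(nrow(.DIRS2D)), function(r)
                     mergeItems(lapply(bySlice, `[[`, r))),
      "25d_mrg"  = list(mergeItems(unlist(bySlice, recursive = FALSE))))
  }
  list(family = "glrlm", aggregation = aggregation, items = items)
}

## ---- zones (GLSZM / GLDZM) ----

## Connected components of iso-level regions by iterative min-label
## propagation over the given neighbourhood offsets (both directions).
.zoneLabels <- function(lv, offs) {
  lab <- array(NA_real_, dim(lv))
  lab[!is.na(lv)] <- which(!is.na(lv))
  repeat {
    new <- lab
    for (r in seq_len(nrow(offs))) {
      nbLab <- .shiftArr(lab, .shiftOff <- offs[r, ])
      nbLv <- .shiftArr(lv, .shiftOff)
      cand <- nbLab
      cand[is.na(nbLv) | is.na(lv) | nbLv != lv] <- NA
      new <- pmin(new, cand, na.rm = TRUE)
    }
    new[is.na(lv)] <- NA
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

.zoneTable <- function(lv, lab) {
  idx <- which(!is.na(lab))
  z <- lab[idx]
  tb <- table(z)
  roots <- as.numeric(names(tb))
  data.frame(level = lv[roots], size = as.integer(tb), root = roots)
}

## Chebyshev distance of every in-mask voxel to the VOI morphological edge
## (border voxels have distance 1; image borders count as edge).
.chebDistMap <- function(inMask, offs) {
  mnum <- array(as.numeric(inMask), dim(inMask))
  border <- array(FALSE, dim(inMask))
  for (r in seq_len(nrow(offs))) {
    nb <- .shiftArr(mnum, offs[r, ])
    border <- border | (inMask & (is.na(nb) | nb == 0))
  }
  cur <- array(NA_real_, dim(inMask))
  cur[inMask] <- Inf
  cur[border] <- 1
  repeat {
    best <- cur
    for (r in seq_len(nrow(offs))) {
      cand <- .shiftArr(cur, offs[r, ]) + 1
      cand[is.na(cand)] <- Inf
      best <- pmin(best, cand)
    }
    if (identical(best, cur)) break
    cur <- best
  }
  cur
}

.zoneMatrices <- function(lv, ng, offs) {
  lab <- .zoneLabels(lv, offs)
  zt <- .zoneTable(lv, lab)
  dm <- .chebDistMap(!is.na(lv), offs)
  zd <- vapply(seq_len(nrow(zt)), function(i) {
    min(dm[lab == zt$root[i]], na.rm = TRUE)
  }, numeric(1))
  szm <- matrix(tabulate((zt$size - 1L) * ng + zt$level,
                         nbins = ng * max(zt$size)), ng, max(zt$size))
  dzm <- matrix(tabulate((zd - 1) * ng + zt$level,
                         nbins = ng * max(zd)), ng, max(zd))
  list(szm = szm, dzm = dzm, nVox = sum(!is.na(lv)))
}

#' Build grey-level size-zone and distance-zone matrices
#'
#' Zones are connected components of equal grey level (26-connected in 3-D,
#' 8-connected in 2-D). The GLSZM bins zones by size; the GLDZM bins them by
#' the minimum Chebyshev distance of any zone voxel to the VOI edge
#' (distances start at 1 at border voxels).
#'
#' @param dv a \linkS4class{DiscretisedVoi}.
#' @param aggregation \code{"2d"} (per slice, features averaged),
#'   \code{"25d"} (per-slice matrices merged) or \code{"3d"}.
#' @return list with \code{family = "zones"}, \code{aggregation} and
#'   \code{items}; each item has \code{szm}, \code{dzm} and \code{nVox}.
#' @export
buildZoneMatrices <- function(dv, aggregation = "3d") {
  aggregation <- match.arg(aggregation, .AGG3)
  lv <- dv@levels; ng <- dv@ng
  if (aggregation == "3d")
    return(list(family = "zones", aggregation = aggregation,
                items = list(.zoneMatrices(lv, ng, .allOffsets3d))))
  perSlice <- lapply(.sliceIdx(lv), function(k)
    .zoneMatrices(.slice(lv, k), ng, .allOffsets2d))
  items <- if (aggregation == "2d") perSlice else {
    list(list(szm = .sumMatsPad(lapply(perSlice, `[[`, "szm")),
              dzm = .sumMatsPad(lapply(perSlice, `[[`, "dzm")),
              nVox = sum(vapply(perSlice, `[[`, numeric(1), "nVox"))))
  }
  list(family = "zones", aggregation = aggregation, items = items)
}

## ---- neighbourhood families (NGTDM / NGLDM) ----

.ngtdmCounts <- function(lv, offs, ng) {
  sumNb <- array(0, dim(lv)); cnt <- array(0L, dim(lv))
  for (r in seq_len(nrow(offs))) {
    nb <- .shiftArr(lv, offs[r, ])
    w <- !is.na(nb)
    sumNb[w] <- sumNb[w] + nb[w]
    cnt <- cnt + w
  }
  valid <- !is.na(lv) & cnt > 0
  g <- lv[valid]
  n <- tabulate(g, ng)
  s <- rep(0, ng)
  if (length(g)) {
    dv <- abs(g - sumNb[valid] / cnt[valid])
    agg <- rowsum(dv, g)
    s[as.integer(rownames(agg))] <- agg[, 1L]
  }
  list(n = n, s = s, nVox = sum(valid))
}

.ngldmCounts <- function(lv, offs, ng) {
  dep <- array(0L, dim(lv))
  for (r in seq_len(nrow(offs))) {
    nb <- .shiftArr(lv, offs[r, ])
    eq <- !is.na(lv) & !is.na(nb) & lv == nb
    dep <- dep + eq
  }
  ok <- !is.na(lv)
  j <- dep[ok] + 1L  # dependence count includes the centre voxel
  maxj <- max(j)
  list(counts = matrix(tabulate((j - 1L) * ng + lv[ok], nbins = ng * maxj),
                       ng, maxj),
       nVox = sum(ok))
}

#' Build the neighbourhood grey-tone difference matrix
#'
#' Neighbourhoods are all in-mask voxels within Chebyshev distance 1
#' (26-connected in 3-D, 8-connected in 2-D); voxels without any in-mask
#' neighbour are excluded.
#'
#' @inheritParams buildZoneMatrices
#' @return list with \code{family}, \code{aggregation} and \code{items};
#'   each item has level counts \code{n}, absolute-difference sums \code{s}
#'   and \code{nVox}.
#' @export
buildNGTDM <- function(dv, aggregation = "3d") {
  aggregation <- match.arg(aggregation, .AGG3)
  lv <- dv@levels; ng <- dv@ng
  if (aggregation == "3d")
    return(list(family = "ngtdm", aggregation = aggregation,
                items = list(.ngtdmCounts(lv, .allOffsets3d, ng))))
  perSlice <- lapply(.sliceIdx(lv), function(k)
    .ngtdmCounts(.slice(lv, k), .allOffsets2d, ng))
  items <- if (aggregation == "2d") perSlice else {
    list(list(n = Reduce(`+`, lapply(perSlice, `[[`, "n")),
              s = Reduce(`+`, lapply(perSlice, `[[`, "s")),
              nVox = sum(vapply(perSlice, `[[`, numeric(1), "nVox"))))
  }
  list(family = "ngtdm", aggregation = aggregation, items = items)
}

#' Build the neighbouring grey-level dependence matrix
#'
#' Coarseness parameter alpha = 0 (a neighbour is dependent iff its grey
#' level equals the centre's), Chebyshev distance 1. The dependence count of
#' a voxel is the number of dependent neighbours plus one for the voxel
#' itself.
#'
#' @inheritParams buildZoneMatrices
#' @return list with \code{family}, \code{aggregation} and \code{items};
#'   each item has \code{counts} (grey level x dependence count) and
#'   \code{nVox}.
#' @export
buildNGLDM <- function(dv, aggregation = "3d") {
  aggregation <- match.arg(aggregation, .AGG3)
  lv <- dv@levels; ng <- dv@ng
  if (aggregation == "3d")
    return(list(family = "ngldm", aggregation = aggregation,
                items = list(.ngldmCounts(lv, .allOffsets3d, ng))))
  perSlice <- lapply(.sliceIdx(lv), function(k)
    .ngldmCounts(.slice(lv, k), .allOffsets2d, ng))
  items <- if (aggregation == "2d") perSlice else {
    list(list(counts = .sumMatsPad(lapply(perSlice, `[[`, "counts")),
              nVox = sum(vapply(perSlice, `[[`, numeric(1), "nVox"))))
  }
  list(family = "ngldm", aggregation = aggregation, items = items)
}
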