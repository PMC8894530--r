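# Independent brute-force oracles: plain voxel loops and exhaustive
# enumeration, deliberately written without any of the vectorised machinery
# used by the package.

.inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# Same canonical ordering as the package's direction set (dx varies fastest).
oracleDirs3d <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    o <- c(dx, dy, dz)
    nz <- which(o != 0)
    if (length(nz) && o[nz[1]] > 0) out[[length(out) + 1]] <- o
  }
  out
}

oracleNb26 <- function() {
  out <- list()
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    if (any(c(dx, dy, dz) != 0)) out[[length(out) + 1]] <- c(dx, dy, dz)
  out
}

oracleNb8 <- function() Filter(function(o) o[3] == 0, oracleNb26())

# Symmetric co-occurrence counts for one offset by exhaustive pair listing.
oracleGlcm <- function(lv, off, ng) {
  d <- dim(lv)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z); q <- p + off
    if (is.na(lv[x, y, z]) || !.inGrid(q, d)) next
    lj <- lv[q[1], q[2], q[3]]
    if (is.na(lj)) next
    li <- lv[x, y, z]
    M[li, lj] <- M[li, lj] + 1
    M[lj, li] <- M[lj, li] + 1
  }
  M
}

# Run-length counts for one direction by walking each run explicitly.
oracleRuns <- function(lv, off, ng) {
  d <- dim(lv)
  runs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    if (is.na(lv[x, y, z])) next
    prev <- p - off
    if (.inGrid(prev, d) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
        lv[prev[1], prev[2], prev[3]] == lv[x, y, z]) next  # not a run start
    len <- 1
    q <- p + off
    while (.inGrid(q, d) && !is.na(lv[q[1], q[2], q[3]]) &&
           lv[q[1], q[2], q[3]] == lv[x, y, z]) {
      len <- len + 1
      q <- q + off
    }
    runs[[length(runs) + 1]] <- c(lv[x, y, z], len)
  }
  if (!length(runs)) return(matrix(0, ng, 1))
  maxl <- max(vapply(runs, `[`, numeric(1), 2))
  M <- matrix(0, ng, maxl)
  for (r in runs) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# Connected zones of equal grey level via queue-based flood fill.
oracleZones <- function(lv, nbs) {
  d <- dim(lv)
  seen <- array(FALSE, d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lv[x, y, z]) || seen[x, y, z]) next
    lev <- lv[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- list()
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members[[length(members) + 1]] <- p
      for (o in nbs) {
        q <- p + o
        if (!.inGrid(q, d)) next
        if (seen[q[1], q[2], q[3]] || is.na(lv[q[1], q[2], q[3]])) next
        if (lv[q[1], q[2], q[3]] != lev) next
        seen[q[1], q[2], q[3]] <- TRUE
        queue[[length(queue) + 1]] <- q
      }
    }
    zones[[length(zones) + 1]] <- list(level = lev, members = members)
  }
  zones
}

# Chebyshev distance of a voxel to the VOI edge: 1 + min over all non-mask
# positions (including those just outside the image) of the Chebyshev
# distance minus ... computed directly as min over (a) in-image non-mask
# voxels and (b) image faces.
oracleEdgeDist <- function(mask, p, inPlane = FALSE) {
  d <- dim(mask)
  best <- Inf
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (mask[x, y, z]) next
    if (inPlane && z != p[3]) next
    dv <- abs(c(x, y, z) - p)
    if (inPlane) dv <- dv[1:2]
    best <- min(best, max(dv))
  }
  axes <- if (inPlane) 1:2 else 1:3
  for (ax in axes) best <- min(best, p[ax], d[ax] - p[ax] + 1)
  best
}

# NGTDM entries by explicit neighbourhood scan.
oracleNgtdm <- function(lv, nbs, ng) {
  d <- dim(lv)
  n <- rep(0, ng); s <- rep(0, ng); nVox <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lv[x, y, z])) next
    vals <- c()
    for (o in nbs) {
      q <- c(x, y, z) + o
      if (.inGrid(q, d) && !is.na(lv[q[1], q[2], q[3]]))
        vals <- c(vals, lv[q[1], q[2], q[3]])
    }
    if (!length(vals)) next
    g <- lv[x, y, z]
    n[g] <- n[g] + 1
    s[g] <- s[g] + abs(g - mean(vals))
    nVox <- nVox + 1
  }
  list(n = n, s = s, nVox = nVox)
}

# NGLDM counts (alpha = 0, dependence = equal neighbours + 1).
oracleNgldm <- function(lv, nbs, ng) {
  d <- dim(lv)
  deps <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (is.na(lv[x, y, z])) next
    k <- 0
    for (o in nbs) {
      q <- c(x, y, z) + o
      if (.inGrid(q, d) && !is.na(lv[q[1], q[2], q[3]]) &&
          lv[q[1], q[2], q[3]] == lv[x, y, z]) k <- k + 1
    }
    deps[[length(deps) + 1]] <- c(lv[x, y, z], k + 1)
  }
  maxj <- max(vapply(deps, `[`, numeric(1), 2))
  M <- matrix(0, ng, maxj)
  for (r in deps) M[r[1], r[2]] <- M[r[1], r[2]] + 1
  M
}

# ICC(A,1) from stats::aov mean squares (independent route to the ANOVA).
oracleIcc <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(n), times = k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- anova(stats::aov(y ~ subj + rater, data = df))
  msr <- a["subj", "Mean Sq"]
  msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Exhaustive Fisher's exact p for an r x 2 table with fixed margins.
oracleFisherRx2 <- function(tab) {
  r <- rowSums(tab); c1 <- colSums(tab)[1]; N <- sum(tab)
  logp <- function(x) sum(lchoose(r, x)) - lchoose(N, c1)
  obs <- logp(tab[, 1])
  grids <- lapply(r, function(ri) 0:ri)
  allx <- as.matrix(expand.grid(grids))
  ok <- rowSums(allx) == c1
  allx <- allx[ok, , drop = FALSE]
  lp <- apply(allx, 1, logp)
  sum(exp(lp[lp <= obs + 1e-7]))
}
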