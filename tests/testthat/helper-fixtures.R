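# Fixture builders used across test files. All fixtures are generated in
# code; nothing is read from disk.

# DiscretisedVoi with prescribed integer levels (NA = outside mask), built
# through the public discretisation API (bin centre of level g maps back to
# level g under FBW 0.25 anchored at 0).
makeDV <- function(lv, spacing = 2) {
  lv <- array(as.integer(lv), dim = dim(lv))
  suv <- (lv - 1) * 0.25 + 0.125
  suv[is.na(suv)] <- 0
  sv <- scanVolume(suv, spacing = spacing, unit = "SUV")
  discretiseFBW(sv, voiMask(!is.na(lv), label = "fix"), bin_width = 0.25)
}

# Random small grid of grey levels with a random (mostly dense) mask.
randomLevelGrid <- function(dmax = c(6, 6, 4), nglev = 4, pmask = 0.85) {
  d <- c(sample(2:dmax[1], 1), sample(2:dmax[2], 1), sample(1:dmax[3], 1))
  lv <- array(sample.int(nglev, prod(d), replace = TRUE), dim = d)
  m <- array(runif(prod(d)) < pmask, dim = d)
  if (sum(m) < 2) m[seq_len(2)] <- TRUE
  lv[!m] <- NA
  lv
}

# A small SUV scan + mask pair with heterogeneous values.
makeSuvVoi <- function(vals, spacing = 2) {
  vals <- array(vals, dim = dim(vals))
  mask <- !is.na(vals)
  v2 <- vals; v2[!mask] <- 0
  list(scan = scanVolume(v2, spacing = spacing, unit = "SUV"),
       voi = voiMask(mask, label = "fix"))
}

# Tiny phantom spec for fast end-to-end runs.
tinySpec <- function(pid = "P01", lesions = list(lesionSpec(c(0, 0, 0), 10)),
                     grid = 24L, counts = 2e5, seed = 1L) {
  phantomSpec(gridShape = grid, voxelSize = 4, bodyRadii = c(40, 40, 44),
              organs = list(), backgroundVois = list(
                list(name = "muscle", centre = c(0, 0, -22), diameter = 24)),
              lesions = lesions, totalCounts = counts,
              meta = scanMeta(patientId = pid), seed = seed)
}
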