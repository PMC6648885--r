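# Independent brute-force oracles for the texture-matrix engines, written
# as direct transliterations of the definitions (per-voxel loops, no shared
# code with the implementation), plus small fixture builders.

# random VOI fixture: levels array with NA holes, wrapped in package objects
randomVoiFixture <- function(dims = c(4, 4, 2), ng = 3, holeProb = 0.2) {
  n <- prod(dims)
  lev <- array(sample.int(ng, n, replace = TRUE), dim = dims)
  lev[runif(n) < holeProb] <- NA
  if (sum(!is.na(lev)) < 2) lev[1:2] <- 1L    # keep VOI usable
  lev
}

# wrap a raw level array as a DiscretizedVoi (levels are taken as given)
asDisc <- function(lev) {
  new("DiscretizedVoi", levels = lev, ng = max(lev, na.rm = TRUE))
}

# volume+mask pair whose discretization under binCount = ng reproduces an
# integer level array exactly (values placed at bin centres)
volumeFromLevels <- function(lev, ng = max(lev, na.rm = TRUE),
                             spacing = c(1, 1, 1)) {
  vals <- array(0, dim = dim(lev))
  if (ng == 1) {
    vals[!is.na(lev)] <- 0.5
  } else {
    vals[!is.na(lev)] <- (lev[!is.na(lev)] - 0.5) / ng
  }
  list(volume = QsmVolume(vals, spacing),
       mask = VoiMask(!is.na(lev)),
       config = studyConfig(binCount = ng))
}

inGrid <- function(v, d) all(v >= 1) && all(v <= d)

# GLCM oracle: loop every voxel, count ordered pair (v, v+off), symmetrize
bruteGlcm <- function(lev, off) {
  d <- dim(lev); ng <- max(lev, na.rm = TRUE)
  P <- matrix(0, ng, ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (is.na(lev[i, j, k])) next
    v2 <- c(i, j, k) + off
    if (!inGrid(v2, d) || is.na(lev[v2[1], v2[2], v2[3]])) next
    a <- lev[i, j, k]; b <- lev[v2[1], v2[2], v2[3]]
    P[a, b] <- P[a, b] + 1
  }
  P + t(P)
}

# GLRLM oracle: walk each lattice line in direction off, run-length encode
bruteGlrlm <- function(lev, off) {
  d <- dim(lev); ng <- max(lev, na.rm = TRUE)
  runs <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- c(i, j, k)
    if (is.na(lev[i, j, k])) next
    prev <- v - off
    prevOk <- inGrid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
      lev[prev[1], prev[2], prev[3]] == lev[i, j, k]
    if (prevOk) next                       # not a run start
    len <- 0L; cur <- v
    while (inGrid(cur, d) && !is.na(lev[cur[1], cur[2], cur[3]]) &&
           lev[cur[1], cur[2], cur[3]] == lev[i, j, k]) {
      len <- len + 1L; cur <- cur + off
    }
    runs[[length(runs) + 1L]] <- c(lev[i, j, k], len)
  }
  if (!length(runs)) return(matrix(0, ng, 1))
  rl <- do.call(rbind, runs)
  P <- matrix(0, ng, max(rl[, 2]))
  for (r in seq_len(nrow(rl))) P[rl[r, 1], rl[r, 2]] <- P[rl[r, 1], rl[r, 2]] + 1
  P
}

# all 26 neighbour offsets
allOffsets26 <- function() {
  g <- expand.grid(-1:1, -1:1, -1:1)
  as.matrix(g[rowSums(abs(g)) > 0, ])
}

# GLSZM oracle: flood fill zones of equal level, 26-connectivity
bruteGlszm <- function(lev) {
  d <- dim(lev); ng <- max(lev, na.rm = TRUE)
  seen <- array(FALSE, dim = d)
  offs <- allOffsets26()
  zones <- list()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v0 <- idx[r, ]
    if (seen[v0[1], v0[2], v0[3]]) next
    lv <- lev[v0[1], v0[2], v0[3]]
    stack <- list(v0); seen[v0[1], v0[2], v0[3]] <- TRUE; size <- 0L
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (o in seq_len(nrow(offs))) {
        w <- v + offs[o, ]
        if (inGrid(w, d) && !seen[w[1], w[2], w[3]] &&
            !is.na(lev[w[1], w[2], w[3]]) &&
            lev[w[1], w[2], w[3]] == lv) {
          seen[w[1], w[2], w[3]] <- TRUE
          stack[[length(stack) + 1L]] <- w
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  zs <- do.call(rbind, zones)
  P <- matrix(0, ng, max(zs[, 2]))
  for (r in seq_len(nrow(zs))) P[zs[r, 1], zs[r, 2]] <- P[zs[r, 1], zs[r, 2]] + 1
  P
}

# GLDM oracle: per voxel, count equal-level 26-neighbours inside the VOI
bruteGldm <- function(lev) {
  d <- dim(lev); ng <- max(lev, na.rm = TRUE)
  offs <- allOffsets26()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  recs <- matrix(0L, nrow(idx), 2)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]; lv <- lev[v[1], v[2], v[3]]; cnt <- 0L
    for (o in seq_len(nrow(offs))) {
      w <- v + offs[o, ]
      if (inGrid(w, d) && !is.na(lev[w[1], w[2], w[3]]) &&
          lev[w[1], w[2], w[3]] == lv) cnt <- cnt + 1L
    }
    recs[r, ] <- c(lv, cnt)
  }
  P <- matrix(0, ng, max(recs[, 2]) + 1L)
  for (r in seq_len(nrow(recs)))
    P[recs[r, 1], recs[r, 2] + 1L] <- P[recs[r, 1], recs[r, 2] + 1L] + 1
  P
}

# NGTDM oracle: per level, summed |level - mean of in-VOI neighbours|
bruteNgtdm <- function(lev) {
  d <- dim(lev); ng <- max(lev, na.rm = TRUE)
  offs <- allOffsets26()
  s <- numeric(ng); n <- numeric(ng)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]; lv <- lev[v[1], v[2], v[3]]
    nb <- c()
    for (o in seq_len(nrow(offs))) {
      w <- v + offs[o, ]
      if (inGrid(w, d) && !is.na(lev[w[1], w[2], w[3]]))
        nb <- c(nb, lev[w[1], w[2], w[3]])
    }
    if (length(nb)) {
      s[lv] <- s[lv] + abs(lv - mean(nb))
      n[lv] <- n[lv] + 1
    }
  }
  list(s = s, n = n)
}

# closed-form AUC for two Gaussian classes
binormalAuc <- function(mu1, sd1, mu0, sd0) {
  pnorm((mu1 - mu0) / sqrt(sd1^2 + sd0^2))
}
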