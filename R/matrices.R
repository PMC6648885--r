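# Gray-level matrix engines. All five operate on the integer level array of
# a DiscretizedVoi (NA outside the VOI) restricted to the mask bounding box;
# distances are counted in voxel steps on the lattice, ignoring anisotropic
# spacing. A "GrayLevelMatrix" is a plain list with class attribute: family,
# counts (or NGTDM vectors), the normalised matrix, and size parameters.

.grayLevelMatrix <- function(family, counts, nz, extra = list()) {
  out <- c(list(family = family, counts = counts, nz = nz,
                p = if (nz > 0) counts / nz else counts), extra)
  class(out) <- "grayLevelMatrix"
  out
}

#' @export
print.grayLevelMatrix <- function(x, ...) {
  cat(sprintf("<%s matrix> %s, Nz = %g\n", x$family,
              paste(dim(x$counts), collapse = "x"), x$nz))
  invisible(x)
}

.levelArray <- function(disc) cropToMask(disc@levels)

#' Gray-level co-occurrence matrix (GLCM)
#'
#' Counts, for one lattice offset at distance delta = 1 voxel step, every
#' ordered pair of in-VOI voxels (v, v + offset) by their gray levels, then
#' symmetrizes (adds the transpose) and normalises. Entry p(i, j) is the
#' relative frequency of the co-occurrence of levels i and j along that
#' direction.
#'
#' @param disc a [DiscretizedVoi-class].
#' @param offset integer(3) lattice offset (a row of [directionSet()]).
#' @return A `grayLevelMatrix` (family "GLCM") with fields `counts`
#'   (symmetrized Ng x Ng), `p` (normalised), `nz` (number of pair
#'   counts) and `offset`; `nz = 0` flags a direction with no valid pair.
#' @export
glcmMatrix <- function(disc, offset) {
  L <- .levelArray(disc)
  ng <- disc@ng
  B <- shiftArray(L, offset)
  ok <- !is.na(L) & !is.na(B)
  counts <- matrix(0, ng, ng)
  if (any(ok)) {
    tab <- table(factor(L[ok], levels = 1:ng), factor(B[ok], levels = 1:ng))
    counts <- unclass(tab) + t(unclass(tab))   # symmetrize
  } else {
    logNote("GLCM: no valid pair for offset (%d,%d,%d)",
            offset[1], offset[2], offset[3])
  }
  dimnames(counts) <- NULL
  .grayLevelMatrix("GLCM", counts, sum(counts), list(offset = offset))
}

#' Gray-level run-length matrix (GLRLM)
#'
#' P(i, j) counts the maximal runs of consecutive voxels of gray level i
#' and run length j along one lattice direction; runs are truncated at the
#' VOI boundary. Entry (i, j) is stored at column j.
#'
#' @inheritParams glcmMatrix
#' @return A `grayLevelMatrix` (family "GLRLM") with `counts` (Ng x Nrmax),
#'   `nz` = Nr (total number of runs) and `np` (number of VOI voxels).
#' @export
glrlmMatrix <- function(disc, offset) {
  L <- .levelArray(disc)
  ng <- disc@ng
  d <- dim(L)
  inv <- !is.na(L)
  np <- sum(inv)
  nxt <- shiftArray(L, offset)                       # level of successor
  same <- inv & !is.na(nxt) & (L == nxt)             # continues forward
  prv <- shiftArray(L, -offset)
  isStart <- inv & (is.na(prv) | L != prv)
  # run length by backward recursion along the direction: process voxels in
  # decreasing projection so the successor's length is already known.
  idx <- which(inv)
  ai <- arrayInd(idx, d)
  proj <- ai %*% matrix(as.numeric(offset), 3, 1)
  len <- integer(prod(d))
  step <- offset[1] + offset[2] * d[1] + offset[3] * d[1] * d[2]
  for (s in sort(unique(proj[, 1]), decreasing = TRUE)) {
    v <- idx[proj[, 1] == s]
    l <- rep.int(1L, length(v))
    sm <- same[v]                       # successor index valid iff same
    if (any(sm)) l[sm] <- 1L + len[v[sm] + step]
    len[v] <- l
  }
  starts <- which(isStart)
  if (!length(starts)) {
    return(.grayLevelMatrix("GLRLM", matrix(0, ng, 1), 0,
                            list(np = np, offset = offset)))
  }
  rl <- len[starts]
  lv <- L[starts]
  counts <- matrix(0, ng, max(rl))
  for (r in seq_along(starts))
    counts[lv[r], rl[r]] <- counts[lv[r], rl[r]] + 1
  .grayLevelMatrix("GLRLM", counts, sum(counts),
                   list(np = np, offset = offset))
}

# 26-neighbourhood offsets: the 13 canonical directions and their negations.
.allNeighborOffsets <- function() {
  d <- directionSet()
  rbind(d, -d)
}

#' Gray-level size-zone matrix (GLSZM)
#'
#' P(i, j) counts the connected zones of gray level i and zone size j
#' voxels, under 26-connectivity; direction-free (one matrix per VOI).
#' Zone membership is resolved with an undirected graph over same-level
#' neighbouring voxels (igraph connected components).
#'
#' @param disc a [DiscretizedVoi-class].
#' @return A `grayLevelMatrix` (family "GLSZM") with `counts`
#'   (Ng x max zone size), `nz` = Ns (number of zones), `np` (VOI voxels).
#' @export
glszmMatrix <- function(disc) {
  L <- .levelArray(disc)
  ng <- disc@ng
  d <- dim(L)
  inv <- which(!is.na(L))
  np <- length(inv)
  vid <- integer(prod(d)); vid[inv] <- seq_along(inv)
  edges <- NULL
  for (k in seq_len(13)) {
    off <- directionSet()[k, ]
    B <- shiftArray(L, off)
    ok <- which(!is.na(L) & !is.na(B) & L == B)
    if (length(ok)) {
      step <- off[1] + off[2] * d[1] + off[3] * d[1] * d[2]
      edges <- rbind(edges, cbind(vid[ok], vid[ok + step]))
    }
  }
  if (is.null(edges)) {
    memb <- seq_len(np)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, np - igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_len(np)]
  }
  # zone level = level of any member (all equal by construction)
  sizes <- tabulate(memb)
  lvOfZone <- vapply(split(L[inv], memb), `[`, integer(1), 1L)
  counts <- matrix(0, ng, max(sizes))
  for (z in seq_along(sizes))
    counts[lvOfZone[z], sizes[z]] <- counts[lvOfZone[z], sizes[z]] + 1
  .grayLevelMatrix("GLSZM", counts, sum(counts), list(np = np))
}

#' Gray-level dependence matrix (GLDM)
#'
#' A neighbour within the 26-neighbourhood is *dependent* on the centre
#' voxel when their gray levels are equal (tolerance alpha = 0). P(i, j+1)
#' counts the VOI voxels of level i with exactly j dependent in-VOI
#' neighbours (column 1 holds j = 0). Every VOI voxel contributes once,
#' so Nz equals the VOI size.
#'
#' @param disc a [DiscretizedVoi-class].
#' @return A `grayLevelMatrix` (family "GLDM") with `counts`
#'   (Ng x (max dependence + 1)), `nz` = number of VOI voxels.
#' @export
gldmMatrix <- function(disc) {
  L <- .levelArray(disc)
  ng <- disc@ng
  inv <- !is.na(L)
  dep <- array(0L, dim = dim(L))
  offs <- .allNeighborOffsets()
  for (k in seq_len(nrow(offs))) {
    B <- shiftArray(L, offs[k, ])
    dep <- dep + (inv & !is.na(B) & L == B)
  }
  lv <- L[inv]; dp <- dep[inv]
  counts <- matrix(0, ng, max(dp) + 1L)
  for (v in seq_along(lv))
    counts[lv[v], dp[v] + 1L] <- counts[lv[v], dp[v] + 1L] + 1
  .grayLevelMatrix("GLDM", counts, sum(counts), list())
}

#' Neighbouring gray-tone difference matrix (NGTDM)
#'
#' For each gray level i: `n_i` counts the VOI voxels of level i having at
#' least one in-VOI 26-neighbour, `p_i = n_i / Nvp`, and `s_i` sums
#' |i - mean level of the voxel's in-VOI neighbours| over those voxels.
#'
#' @param disc a [DiscretizedVoi-class].
#' @return A `grayLevelMatrix` (family "NGTDM") with vectors `s`, `n`,
#'   `pLevel` (length Ng) and `nvp`.
#' @export
ngtdmMatrix <- function(disc) {
  L <- .levelArray(disc)
  ng <- disc@ng
  inv <- !is.na(L)
  nbSum <- array(0, dim = dim(L))
  nbCnt <- array(0L, dim = dim(L))
  offs <- .allNeighborOffsets()
  for (k in seq_len(nrow(offs))) {
    B <- shiftArray(L, offs[k, ])
    has <- !is.na(B)
    nbSum[has] <- nbSum[has] + B[has]
    nbCnt <- nbCnt + has
  }
  use <- inv & nbCnt > 0L
  lv <- L[use]
  diffs <- abs(lv - nbSum[use] / nbCnt[use])
  s <- vapply(1:ng, function(i) sum(diffs[lv == i]), numeric(1))
  n <- vapply(1:ng, function(i) sum(lv == i), numeric(1))
  nvp <- sum(n)
  .grayLevelMatrix("NGTDM", NULL, nvp,
                   list(s = s, n = n,
                        pLevel = if (nvp > 0) n / nvp else n, nvp = nvp))
}
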