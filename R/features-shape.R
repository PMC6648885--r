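# Shape features of the binary VOI in physical (mm) coordinates.

# Triangulated surface of the voxelized VOI: every mask face exposed to a
# non-mask (or out-of-grid) voxel contributes one rectangular face = two
# triangles. Returns total area (mm^2) and the unique face-corner vertices
# in mm. A single 1x1x1 mm voxel thus has area 6 and its Maximum3DDiameter
# is the cube diagonal sqrt(3).
.voiSurface <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  faceArea <- c(spacing[2] * spacing[3],   # faces normal to x
                spacing[1] * spacing[3],   # normal to y
                spacing[1] * spacing[2])   # normal to z
  area <- 0
  verts <- NULL
  m <- array(FALSE, dim = d + 2L)          # padded occupancy
  m[cbind(idx[, 1] + 1L, idx[, 2] + 1L, idx[, 3] + 1L)] <- TRUE
  for (ax in 1:3) {
    for (sgn in c(-1L, 1L)) {
      off <- integer(3); off[ax] <- sgn
      nb <- m[cbind(idx[, 1] + 1L + off[1], idx[, 2] + 1L + off[2],
                    idx[, 3] + 1L + off[3])]
      exposed <- idx[!nb, , drop = FALSE]
      nf <- nrow(exposed)
      if (nf == 0) next
      area <- area + nf * faceArea[ax]
      # the 4 corners of each exposed face, in voxel units then mm
      oth <- setdiff(1:3, ax)
      for (s1 in c(-0.5, 0.5)) for (s2 in c(-0.5, 0.5)) {
        v <- exposed
        v[, ax] <- v[, ax] + sgn * 0.5
        v[, oth[1]] <- v[, oth[1]] + s1
        v[, oth[2]] <- v[, oth[2]] + s2
        verts <- rbind(verts, v)
      }
    }
  }
  verts <- unique(verts)
  verts <- sweep(verts, 2, spacing, `*`)
  list(area = area, vertices = verts)
}

.maxPairDist <- function(pts) {
  if (is.null(pts) || nrow(pts) < 2) return(0)
  # convex-hull-free but chunked to bound memory
  n <- nrow(pts)
  best <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    i <- i0:min(n, i0 + step - 1L)
    dmat <- outer(rowSums(pts[i, , drop = FALSE]^2), rowSums(pts^2), `+`) -
      2 * pts[i, , drop = FALSE] %*% t(pts)
    best <- max(best, max(dmat))
  }
  sqrt(max(best, 0))
}

# Max in-plane diameter among surface vertices sharing a coordinate on the
# excluded axis (planes through the voxel-face lattice).
.max2dDiameter <- function(verts, dropAxis) {
  keep <- setdiff(1:3, dropAxis)
  groups <- split(seq_len(nrow(verts)), verts[, dropAxis])
  max(vapply(groups, function(g)
    .maxPairDist(verts[g, keep, drop = FALSE]), numeric(1)))
}

#' Shape features of the VOI
#'
#' The 13 geometry features of the binary VOI. `Volume` is the voxel
#' count (the convention used when reporting group differences); surface
#' quantities come from the triangulated boundary of the voxelized mask;
#' the three axis lengths derive from the principal axes (eigenvalues
#' lambda of the covariance of the physical voxel-center coordinates,
#' axis length = 4*sqrt(lambda)); Sphericity and SurfaceVolumeRatio use
#' the physical volume (voxel count x voxel volume in mm^3).
#'
#' @param mask a [VoiMask-class] (non-empty).
#' @param spacing numeric(3) voxel spacing in mm.
#' @return named numeric(13), names `shape_*` in canonical order.
#' @export
shapeFeatures <- function(mask, spacing = c(0.86, 0.86, 1.0)) {
  m <- mask@mask
  if (!any(m)) stop("degenerate VOI: mask is empty")
  nvox <- sum(m)
  physVol <- nvox * prod(spacing)
  surf <- .voiSurface(m, spacing)
  coords <- which(m, arr.ind = TRUE)
  coords <- sweep(coords, 2, spacing, `*`)
  if (nvox > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev[ev < 0] <- 0
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0
  if (ev[1] <= 0 || ev[3] <= 0)
    logNote("degenerate VOI geometry: zero principal eigenvalue")
  vals <- c(
    Volume = nvox,
    SurfaceArea = surf$area,
    SurfaceVolumeRatio = surf$area / physVol,
    Sphericity = (36 * pi * physVol^2)^(1 / 3) / surf$area,
    Maximum3DDiameter = .maxPairDist(surf$vertices),
    Maximum2DDiameterSlice = .max2dDiameter(surf$vertices, 3L),
    Maximum2DDiameterColumn = .max2dDiameter(surf$vertices, 2L),
    Maximum2DDiameterRow = .max2dDiameter(surf$vertices, 1L),
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = elong,
    Flatness = flat)
  setNames(as.numeric(vals), featureNames105("shape"))
}
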