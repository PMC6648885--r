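#' The 13 unique lattice directions for 3D texture matrices
#'
#' Angular sampling used by the GLCM, GLRLM and (through its neighbourhood)
#' GLDM/NGTDM engines: the 13 unique axes of the 26-neighbourhood at
#' distance one voxel step — the 3 lattice axes, the 6 face diagonals and
#' the 4 body diagonals, one sign representative each. No offset is the
#' negation of another; together with their negations they tile the full
#' 26-neighbourhood.
#'
#' @return A 13 x 3 integer matrix, one offset per row.
#' @export
directionSet <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
    c(1, -1, 0), c(1, 0, -1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  storage.mode(m) <- "integer"
  m
}

#' Discretize VOI intensities into gray levels
#'
#' Maps the continuous susceptibility values inside the VOI to integer
#' gray levels 1..Ng, as required by every texture matrix. Two policies:
#'
#' * fixed bin count `Nb`: `level = 1 + floor((x - min) / (max - min) * Nb)`,
#'   clamped to `Nb` (the maximum maps into the top bin);
#' * fixed bin width `w` (ppm): `level = 1 + floor((x - min) / w)`.
#'
#' A constant VOI under either policy yields a single level 1 (Ng = 1).
#'
#' @param volume a [QsmVolume-class].
#' @param mask a [VoiMask-class] on the same grid (non-empty).
#' @param config a [StudyConfig-class] carrying the binning policy.
#' @return A [DiscretizedVoi-class]; non-VOI voxels are NA.
#' @export
discretizeVoi <- function(volume, mask, config = studyConfig()) {
  stopifnot(identical(dim(volume@values), dim(mask@mask)))
  if (!any(mask@mask)) stop("degenerate VOI: mask is empty")
  x <- volume@values[mask@mask]
  if (any(!is.finite(x))) stop("non-finite susceptibility values in VOI")
  lo <- min(x); hi <- max(x)
  if (!is.na(config@binCount)) {
    nb <- config@binCount
    if (hi == lo) {
      lev <- rep.int(1L, length(x))
      logNote("constant VOI: single gray level")
    } else {
      lev <- 1L + as.integer(floor((x - lo) / (hi - lo) * nb))
      lev[lev > nb] <- nb
    }
  } else {
    lev <- 1L + as.integer(floor((x - lo) / config@binWidth))
  }
  arr <- array(NA_integer_, dim = dim(mask@mask))
  arr[mask@mask] <- lev
  new("DiscretizedVoi", levels = arr, ng = max(lev))
}
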