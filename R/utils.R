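# Small shared internals.

# Quiet, opt-in log channel for degenerate-case notes (enable with
# options(qsmRadiomics.verbose = TRUE)); the CLI turns it on.
logNote <- function(...) {
  if (isTRUE(getOption("qsmRadiomics.verbose", FALSE)))
    message("[qsmRadiomics] ", sprintf(...))
  invisible(NULL)
}

# log2 with the 0*log0 = 0 convention applied by callers through this eps.
xlog2 <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}

# Shift a 3D array by an integer offset, filling exposed cells.
# Element [i,j,k] of the result is a[i+off1, j+off2, k+off3] (fill outside).
shiftArray <- function(a, off, fill = NA) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      dst[[ax]] <- seq_len(d[ax] - o)
      src[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      dst[[ax]] <- seq_len(d[ax] + o) - o
      src[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Crop levels array to the mask bounding box (plus optional 1-voxel pad).
cropToMask <- function(a, pad = 0L) {
  idx <- which(!is.na(a), arr.ind = TRUE)
  d <- dim(a)
  rng <- lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - pad)
    hi <- min(d[ax], max(idx[, ax]) + pad)
    lo:hi
  })
  a[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
}

# Population (ML, denominator n) central moments.
popMoment <- function(x, k) mean((x - mean(x))^k)
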