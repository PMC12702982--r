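#' @useDynLib osteosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
#' @importFrom stats rbinom rpois runif rnorm median coef lm quantile setNames uniroot approx pnorm
#' @importFrom utils head tail write.csv read.csv
NULL

# Shift a 3D array by one voxel along an axis with replicate (zero-gradient)
# padding; used by the diffusion stencil and surface extraction.
shift3d <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- idx[[axis]] - by
  src[src < 1L] <- 1L
  src[src > d[axis]] <- d[axis]
  idx[[axis]] <- src
  a[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

# Linear voxel index from integer coordinates (1-based, dim = c(nx, ny, nz)).
vox_index <- function(i, j, k, d) {
  i + (j - 1L) * d[1L] + (k - 1L) * d[1L] * d[2L]
}

vox_coords <- function(idx, d) {
  idx0 <- idx - 1L
  k <- idx0 %/% (d[1L] * d[2L])
  r <- idx0 %% (d[1L] * d[2L])
  j <- r %/% d[1L]
  i <- r %% d[1L]
  cbind(i = i + 1L, j = j + 1L, k = k + 1L)
}

# Face-neighbor linear offsets that stay in bounds; returns a matrix of
# neighbor indices (NA where out of bounds) for the supplied voxel indices.
face_neighbors <- function(idx, d) {
  co <- vox_coords(idx, d)
  out <- matrix(NA_integer_, nrow = length(idx), ncol = 6L)
  shifts <- rbind(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
                  c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (s in seq_len(6L)) {
    i <- co[, 1L] + shifts[s, 1L]
    j <- co[, 2L] + shifts[s, 2L]
    k <- co[, 3L] + shifts[s, 3L]
    ok <- i >= 1L & i <= d[1L] & j >= 1L & j <= d[2L] & k >= 1L & k <= d[3L]
    out[ok, s] <- vox_index(i[ok], j[ok], k[ok], d)
  }
  out
}

# Deterministic child seed derivation: all module streams hang off one master
# seed so identical configs reproduce bit-identical runs (kept below 2^31).
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 100000L) * 11717L + match(stream, c(
    "phantom", "seeding", "cells", "cytokines", "motility", "engine",
    "stats", "misc")) * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
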