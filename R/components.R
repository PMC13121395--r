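# Connected-component and distance primitives on 3-D logical arrays.
#
# A lesion mask is defined as one 26-connected component containing the seed
# voxel. The frontier-based breadth-first growth below is vectorised over the
# current frontier; the array is padded with a one-voxel FALSE border so the
# 26 linear neighbour offsets never wrap across grid faces.

# linear offsets of the 26-neighbourhood in an array with dims `dp`
neighbour_offsets_26 <- function(dp) {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off[, 1] + off[, 2] * dp[1] + off[, 3] * dp[1] * dp[2]
}

# 26-connected component of `candidate` (logical 3-D array) containing `seed`
# (1-based i,j,k). Returns a logical array of the same dims; all-FALSE when
# the seed voxel itself is not a candidate.
seeded_component <- function(candidate, seed) {
  d <- dim(candidate)
  out <- array(FALSE, d)
  if (!candidate[seed[1], seed[2], seed[3]]) return(out)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- candidate
  loff <- neighbour_offsets_26(dp)
  seedlin <- (seed[1] + 1L) +
    seed[2] * dp[1] +
    seed[3] * dp[1] * dp[2]
  visited <- logical(prod(dp))
  visited[seedlin] <- TRUE
  frontier <- seedlin
  while (length(frontier)) {
    nb <- unique(rep(frontier, each = 26L) + loff)
    nb <- nb[pad[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  dim(visited) <- dp
  out[] <- visited[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  out
}

# voxel coordinates (n x 3 integer matrix) of TRUE voxels
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# 6-surface of a mask: mask voxels with at least one axis neighbour outside
# the mask (out-of-grid counts as outside). The nearest mask voxel to any
# exterior point is always on this surface, so exterior distances to the mask
# can be computed against surface voxels only.
surface_coords <- function(mask) {
  d <- dim(mask)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  sh <- function(a, di, dj, dk) {
    i <- (2:(d[1] + 1L)) + di; j <- (2:(d[2] + 1L)) + dj; k <- (2:(d[3] + 1L)) + dk
    pad[i, j, k, drop = FALSE]
  }
  core <- sh(pad, 0L, 0L, 0L) &
    sh(pad, 1L, 0L, 0L) & sh(pad, -1L, 0L, 0L) &
    sh(pad, 0L, 1L, 0L) & sh(pad, 0L, -1L, 0L) &
    sh(pad, 0L, 0L, 1L) & sh(pad, 0L, 0L, -1L)
  surf <- mask & !core
  which(surf, arr.ind = TRUE)
}

# For each candidate voxel (rows of `cand`, 1-based coords), the Euclidean
# distance in mm to the nearest voxel among `targets`, honouring anisotropic
# spacing. Chunked pairwise computation to bound memory.
min_dist_mm <- function(cand, targets, spacing, chunk = 4000L) {
  if (nrow(targets) == 0L) return(rep(Inf, nrow(cand)))
  tx <- targets[, 1] * spacing[1]
  ty <- targets[, 2] * spacing[2]
  tz <- targets[, 3] * spacing[3]
  n <- nrow(cand)
  out <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx <- outer(cand[idx, 1] * spacing[1], tx, "-")
    dy <- outer(cand[idx, 2] * spacing[2], ty, "-")
    dz <- outer(cand[idx, 3] * spacing[3], tz, "-")
    d2 <- dx * dx + dy * dy + dz * dz
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}
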