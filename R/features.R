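#' Lesion SUVpeak (1 mL sphere mean)
#'
#' The maximum, over sphere centres inside the mask, of the mean SUV within a
#' sphere of volume `sphere_ml` (1.0 mL by default, diameter about 12.4 mm)
#' centred at that voxel. Sphere voxels outside the mask contribute to the
#' mean; voxels outside the grid are excluded (the mean is taken over the
#' in-grid part of the sphere).
#'
#' @param vol an [suv_volume].
#' @param mask logical array of the lesion mask (non-empty).
#' @param sphere_ml sphere volume in mL.
#' @return SUVpeak, a single number.
#' @export
suv_peak <- function(vol, mask, sphere_ml = 1.0) {
  if (!any(mask)) stop("SUVpeak is undefined for an empty mask", call. = FALSE)
  off <- sphere_offsets(vol$spacing, sphere_ml)
  centres <- mask_coords(mask)
  d <- dim(vol$values)
  n <- nrow(centres)
  sums <- numeric(n)
  cnts <- numeric(n)
  for (r in seq_len(nrow(off))) {
    i <- centres[, 1] + off[r, 1]
    j <- centres[, 2] + off[r, 2]
    k <- centres[, 3] + off[r, 3]
    ok <- i >= 1L & i <= d[1] & j >= 1L & j <= d[2] & k >= 1L & k <= d[3]
    if (!any(ok)) next
    lin <- i[ok] + (j[ok] - 1L) * d[1] + (k[ok] - 1L) * d[1] * d[2]
    sums[ok] <- sums[ok] + vol$values[lin]
    cnts[ok] <- cnts[ok] + 1
  }
  max(sums / cnts)
}

# integer voxel offsets whose centres lie within the radius of a sphere of
# `sphere_ml` millilitres, given anisotropic spacing
sphere_offsets <- function(spacing, sphere_ml = 1.0) {
  r_mm <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  rv <- ceiling(r_mm / spacing)
  g <- as.matrix(expand.grid(di = -rv[1]:rv[1], dj = -rv[2]:rv[2], dk = -rv[3]:rv[3]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 + (g[, 3] * spacing[3])^2
  g[d2 <= r_mm^2, , drop = FALSE]
}

#' Local background SUV in a shell around a lesion
#'
#' Mean SUV over the voxels whose Euclidean distance (mm, anisotropy-aware)
#' from the mask surface lies within `shell_mm` (default 10 to 15 mm, i.e.
#' +1 to +1.5 cm beyond the lesion contour), excluding the lesion itself and
#' any voxel of the `exclusions` masks (e.g. neighbouring lesions).
#'
#' @inheritParams suv_peak
#' @param exclusions list of logical arrays to exclude from the shell.
#' @param shell_mm closed distance bounds of the shell, mm.
#' @return list with `suvbg` (mean shell SUV), `n_voxels`, and `voxels`
#'   (matrix of shell voxel indices).
#' @export
suvbg_shell <- function(vol, mask, exclusions = list(), shell_mm = c(10, 15)) {
  if (!any(mask)) stop("background shell is undefined for an empty mask", call. = FALSE)
  d <- dim(vol$values)
  cm <- mask_coords(mask)
  pad <- ceiling(shell_mm[2] / vol$spacing) + 1L
  lo <- pmax(apply(cm, 2, min) - pad, 1L)
  hi <- pmin(apply(cm, 2, max) + pad, d)
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  lin <- cand[, 1] + (cand[, 2] - 1L) * d[1] + (cand[, 3] - 1L) * d[1] * d[2]
  keep <- !mask[lin]
  excl <- logical(nrow(cand))
  for (e in exclusions) {
    if (!identical(dim(e), d))
      stop("exclusion masks must match the volume dimensions", call. = FALSE)
    excl <- excl | e[lin]
  }
  surf <- surface_coords(mask)
  dist <- min_dist_mm(cand, surf, vol$spacing)
  in_shell <- dist >= shell_mm[1] & dist <= shell_mm[2]
  sel <- keep & in_shell & !excl
  if (!any(sel)) {
    if (any(keep & in_shell))
      stop("background shell fully excluded by exclusion masks", call. = FALSE)
    stop("background shell out of bounds: no voxels within the shell distance inside the grid",
         call. = FALSE)
  }
  list(suvbg = mean(vol$values[lin[sel]]),
       n_voxels = sum(sel),
       voxels = cand[sel, , drop = FALSE])
}

#' Tumour-to-background ratio of SUVpeak
#'
#' @param suvpeak lesion SUVpeak.
#' @param suvbg local background SUV; must be strictly positive.
#' @return `suvpeak / suvbg`.
#' @export
tbr_peak <- function(suvpeak, suvbg) {
  if (any(suvbg <= 0))
    stop("TBRpeak is undefined for SUVbg <= 0", call. = FALSE)
  suvpeak / suvbg
}

#' Metabolic tumour volume of a mask
#'
#' Voxel count times physical voxel volume, in mL. An empty mask has MTV 0.
#'
#' @param mask logical array.
#' @param spacing voxel spacing in mm (length 3).
#' @return volume in mL.
#' @export
mtv <- function(mask, spacing) {
  sum(mask) * voxel_volume_ml(spacing)
}
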