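#' SUV volume container
#'
#' A minimal container for a 3-D grid of standardized uptake values (SUV)
#' together with its physical voxel spacing. All segmentation operators and
#' feature extractors in the package work on this class. World coordinates
#' place the centre of voxel (1,1,1) at `origin`, with axes along the array
#' dimensions (a diagonal affine); voxel indices are 1-based throughout the
#' R interface.
#'
#' @param values numeric 3-D array of SUV values; must be finite and >= 0.
#' @param spacing numeric length-3 vector, voxel spacing in mm (all > 0).
#' @param origin numeric length-3 vector, world position (mm) of the first
#'   voxel centre.
#'
#' @return An object of class `suv_volume`: a list with elements `values`,
#'   `spacing` and `origin`.
#' @export
#' @examples
#' vol <- suv_volume(array(1, c(8, 8, 8)), spacing = c(2, 2, 2))
#' vol
suv_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("SUV values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("SUV values must be >= 0", call. = FALSE)
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  SUV range [%.3g, %.3g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$values)

# volume of one voxel in mL (1 mL = 1000 mm^3)
voxel_volume_ml <- function(spacing) prod(spacing) / 1000

check_seed <- function(vol, seed) {
  seed <- as.integer(seed)
  d <- dim(vol$values)
  if (length(seed) != 3L || any(is.na(seed)))
    stop("`seed` must be three voxel indices (i, j, k)", call. = FALSE)
  if (any(seed < 1L) || any(seed > d))
    stop(sprintf("seed (%s) lies outside the %s grid",
                 paste(seed, collapse = ","), paste(d, collapse = "x")),
         call. = FALSE)
  seed
}

#' Gaussian point-spread blur of a 3-D field
#'
#' Separable Gaussian convolution with zero padding at the grid edges,
#' parameterised by the full width at half maximum (FWHM) in mm — the
#' standard isotropic model for PET scanner resolution. Spacing-aware:
#' the kernel sigma is converted to voxels per axis.
#'
#' @param values numeric 3-D array.
#' @param spacing voxel spacing in mm (length 3).
#' @param fwhm full width at half maximum of the Gaussian in mm; 0 is a no-op.
#' @return blurred array, same dimensions.
#' @export
gaussian_blur <- function(values, spacing, fwhm) {
  stopifnot(is.numeric(fwhm), length(fwhm) == 1L, fwhm >= 0)
  if (fwhm == 0) return(values)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (ax in 1:3) {
    s <- sigma / spacing[ax]
    r <- max(1L, as.integer(ceiling(4 * s)))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    values <- convolve_axis(values, k, ax)
  }
  values
}

# 1-D zero-padded convolution along axis `ax` of a 3-D array
convolve_axis <- function(a, k, ax) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(a, perm)
  dm <- dim(m)
  mm <- matrix(m, nrow = dm[1])
  n <- dm[1]
  out <- matrix(0, n, ncol(mm))
  for (i in seq_along(k)) {
    sh <- i - r - 1L
    src <- seq_len(n) + sh
    ok <- src >= 1L & src <= n
    if (any(ok)) out[ok, ] <- out[ok, ] + k[i] * mm[src[ok], , drop = FALSE]
  }
  dim(out) <- dm
  aperm(out, order(perm))
}
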