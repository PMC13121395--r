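#' Specify a planted lesion for a synthetic phantom
#'
#' @param center physical coordinates (mm) of the lesion centre, length 3.
#' @param radius lesion radius in mm; a single value for a sphere, three
#'   semi-axes for an ellipsoid.
#' @param peak_suv lesion SUV before blurring; must exceed the phantom
#'   background for the lesion to be detectable.
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param timepoint one of `"baseline"`, `"interim"`, `"eot"`.
#' @param location one of `"nodal_above"`, `"nodal_below"`, `"extranodal"`.
#' @return a `lesion_spec` list.
#' @export
lesion_spec <- function(center, radius, peak_suv, shape = c("sphere", "ellipsoid"),
                        timepoint = c("baseline", "interim", "eot"),
                        location = c("nodal_above", "nodal_below", "extranodal")) {
  shape <- match.arg(shape)
  timepoint <- match.arg(timepoint)
  location <- match.arg(location)
  radius <- as.numeric(radius)
  if (shape == "sphere" && length(radius) != 1L)
    stop("a sphere takes a single radius", call. = FALSE)
  if (shape == "ellipsoid" && length(radius) != 3L)
    stop("an ellipsoid takes three semi-axes", call. = FALSE)
  if (any(radius <= 0)) stop("radius must be > 0", call. = FALSE)
  if (peak_suv <= 0) stop("peak_suv must be > 0", call. = FALSE)
  structure(list(center = as.numeric(center), radius = radius,
                 peak_suv = peak_suv, shape = shape,
                 timepoint = timepoint, location = location),
            class = "lesion_spec")
}

#' Specify a synthetic SUV phantom
#'
#' @param grid_shape voxels per axis (length 3).
#' @param spacing mm per axis, strictly positive.
#' @param background_suv uniform background SUV.
#' @param noise_sd standard deviation of additive Gaussian noise (SUV);
#'   noisy values are clipped at 0 so the volume stays a valid SUV image.
#' @param psf_fwhm full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (0 disables blurring).
#' @param lesions list of [lesion_spec] objects.
#' @param rng_seed integer seed; the generator is deterministic given it.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape, spacing, background_suv = 0.5,
                         noise_sd = 0, psf_fwhm = 0, lesions = list(),
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 2L),
            length(spacing) == 3L, all(spacing > 0),
            noise_sd >= 0, psf_fwhm >= 0, background_suv >= 0)
  extent <- (grid_shape - 1L) * spacing
  for (idx in seq_along(lesions)) {
    L <- lesions[[idx]]
    r <- if (length(L$radius) == 1L) rep(L$radius, 3L) else L$radius
    if (any(L$center - r < 0) || any(L$center + r > extent))
      stop(sprintf("lesion %d does not fit inside the volume bounds", idx),
           call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 background_suv = background_suv, noise_sd = noise_sd,
                 psf_fwhm = psf_fwhm, lesions = lesions,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Generate a synthetic SUV volume with planted lesions
#'
#' Builds a uniform-background volume, plants each lesion as a compact
#' region at `peak_suv`, blurs the lesion excess (lesion minus background)
#' with the Gaussian point-spread function, adds the background back, then
#' adds truncated Gaussian noise. Blurring only the lesion excess keeps the
#' background exactly uniform and conserves lesion activity away from the
#' grid edges. One seed per lesion is returned: the voxel of maximum
#' pre-noise SUV inside the planted lesion extent, mirroring a reader
#' clicking the hottest voxel.
#'
#' Overlapping lesions are rejected with a diagnostic naming the colliding
#' lesion indices.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` (an [suv_volume]) and `seeds`, a data frame
#'   with one row per lesion: voxel indices `i, j, k` (1-based), the
#'   pre-noise SUV at the seed, and the lesion's timepoint and location.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  delta <- array(0, d)
  owner <- array(0L, d)
  lesion_vox <- vector("list", length(spec$lesions))
  for (idx in seq_along(spec$lesions)) {
    L <- spec$lesions[[idx]]
    r <- if (length(L$radius) == 1L) rep(L$radius, 3L) else L$radius
    # bounding-box candidates, then exact ellipsoid test on voxel centres
    sub <- lapply(1:3, function(a) which(abs(ax[[a]] - L$center[a]) <= r[a]))
    g <- as.matrix(expand.grid(i = sub[[1]], j = sub[[2]], k = sub[[3]]))
    u <- ((ax[[1]][g[, 1]] - L$center[1]) / r[1])^2 +
         ((ax[[2]][g[, 2]] - L$center[2]) / r[2])^2 +
         ((ax[[3]][g[, 3]] - L$center[3]) / r[3])^2
    g <- g[u <= 1, , drop = FALSE]
    lin <- g[, 1] + (g[, 2] - 1L) * d[1] + (g[, 3] - 1L) * d[1] * d[2]
    clash <- owner[lin] != 0L
    if (any(clash))
      stop(sprintf("lesions %s and %d overlap",
                   paste(unique(owner[lin][clash]), collapse = ","), idx),
           call. = FALSE)
    owner[lin] <- idx
    delta[lin] <- L$peak_suv - spec$background_suv
    lesion_vox[[idx]] <- lin
  }
  if (spec$psf_fwhm > 0)
    delta <- gaussian_blur(delta, sp, spec$psf_fwhm)
  clean <- spec$background_suv + delta
  seeds <- do.call(rbind, lapply(seq_along(spec$lesions), function(idx) {
    lin <- lesion_vox[[idx]]
    best <- lin[which.max(clean[lin])]
    k <- (best - 1L) %/% (d[1] * d[2])
    j <- (best - 1L - k * d[1] * d[2]) %/% d[1]
    i <- best - 1L - k * d[1] * d[2] - j * d[1]
    data.frame(lesion = idx, i = i + 1L, j = j + 1L, k = k + 1L,
               seed_suv = clean[best],
               timepoint = spec$lesions[[idx]]$timepoint,
               location = spec$lesions[[idx]]$location,
               stringsAsFactors = FALSE)
  }))
  values <- clean
  if (spec$noise_sd > 0) {
    set.seed(spec$rng_seed)
    values <- pmax(0, clean + stats::rnorm(length(clean), sd = spec$noise_sd))
    dim(values) <- d
  }
  list(volume = suv_volume(values, sp), seeds = seeds)
}
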