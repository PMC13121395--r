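#' Generate and segment a synthetic lesion cohort
#'
#' Builds one single-lesion phantom per cohort lesion (spread over the three
#' treatment timepoints), runs all six segmentation methods on each, and
#' stacks the per-method records. Lesion peak SUV is drawn log-uniformly and
#' the background uniformly, mirroring the rating simulator's feature
#' distributions; radii, blur and noise are kept in a narrow realistic range
#' so every phantom is segmentable.
#'
#' @param n_per_timepoint integer triple of lesion counts (baseline,
#'   interim, end-of-treatment); defaults to the 409/67/122 cohort split.
#' @param grid_shape voxels per axis of each phantom.
#' @param spacing voxel spacing in mm.
#' @param peak_range lesion peak SUV range (log-uniform draw).
#' @param background_range background SUV range (uniform draw).
#' @param radius_range lesion radius range in mm.
#' @param psf_fwhm scanner blur FWHM in mm.
#' @param noise_sd additive noise SD in SUV.
#' @param rng_seed integer seed; the whole cohort is deterministic given it.
#' @return data frame with 6 rows per lesion: `lesion`, `timepoint`,
#'   `peak_suv`, `background_suv` (simulation truth) plus the
#'   [segment_all()] record columns.
#' @export
segment_cohort <- function(n_per_timepoint = c(baseline = 409, interim = 67, eot = 122),
                           grid_shape = 20L, spacing = 2,
                           peak_range = c(3, 15), background_range = c(0.3, 1.5),
                           radius_range = c(4, 7), psf_fwhm = 5, noise_sd = 0.1,
                           rng_seed = 1L) {
  n <- sum(n_per_timepoint)
  stopifnot(n >= 1L)
  timepoints <- rep(c("baseline", "interim", "eot"), n_per_timepoint)
  set.seed(rng_seed)
  bg <- stats::runif(n, background_range[1], background_range[2])
  peak <- exp(stats::runif(n, log(peak_range[1]), log(peak_range[2])))
  rad <- stats::runif(n, radius_range[1], radius_range[2])
  extent <- (grid_shape - 1L) * spacing
  centres <- matrix(stats::runif(3L * n, 0, 1), ncol = 3L)
  sub_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lo <- rad[i] + spacing
    centre <- lo + centres[i, ] * (extent - 2 * lo)
    g <- generate_volume(phantom_spec(
      grid_shape, spacing, background_suv = bg[i], noise_sd = noise_sd,
      psf_fwhm = psf_fwhm,
      lesions = list(lesion_spec(centre, rad[i], peak[i],
                                 timepoint = timepoints[i])),
      rng_seed = sub_seeds[i]))
    sa <- segment_all(g$volume, as.integer(g$seeds[1, c("i", "j", "k")]))
    rec <- sa$results
    rec$lesion <- i
    rec$timepoint <- timepoints[i]
    rec$peak_suv <- peak[i]
    rec$background_suv <- bg[i]
    out[[i]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("lesion", "timepoint", "peak_suv", "background_suv",
          setdiff(names(res), c("lesion", "timepoint", "peak_suv", "background_suv")))]
}
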