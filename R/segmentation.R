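#' The six segmentation method names
#'
#' Canonical internal names, in the fixed order used throughout the package:
#' two absolute SUV thresholds (`SUV2.5`, `SUV4.0`), a relative threshold at
#' 41% of lesion SUVmax (`41max`), a background-adapted threshold at 50% of
#' SUVpeak (`A50peak`), and majority votes of the four threshold methods at
#' agreement levels 2 (`MV2`) and 3 (`MV3`).
#'
#' @return character vector of length 6.
#' @export
pet_methods <- function() {
  c("SUV2.5", "SUV4.0", "41max", "A50peak", "MV2", "MV3")
}

#' Seeded fixed-threshold segmentation
#'
#' The mask is the 26-connected component of voxels with SUV >= `threshold`
#' that contains the seed voxel (closed threshold convention). If the seed
#' voxel itself is below the threshold the mask is empty.
#'
#' @param vol an [suv_volume].
#' @param seed integer voxel index (i, j, k), 1-based; must lie inside the grid.
#' @param threshold absolute SUV threshold.
#' @return logical 3-D array (the mask).
#' @export
fixed_threshold_mask <- function(vol, seed, threshold) {
  seed <- check_seed(vol, seed)
  seeded_component(vol$values >= threshold, seed)
}

#' Seeded 41%-of-SUVmax segmentation
#'
#' The lesion SUVmax is scouted as the maximum SUV inside the seed's
#' 26-connected component at an absolute SUV `scout_threshold` (the most
#' permissive fixed threshold in the pool); if that scouting component is
#' empty the seed voxel value is used. The returned mask is the seeded
#' component at `fraction` times that SUVmax.
#'
#' @inheritParams fixed_threshold_mask
#' @param fraction relative threshold as a fraction of lesion SUVmax.
#' @param scout_threshold absolute SUV used to scout the lesion extent.
#' @return logical mask, with the applied absolute threshold attached as
#'   attribute `threshold`.
#' @export
relative41_mask <- function(vol, seed, fraction = 0.41, scout_threshold = 2.5) {
  seed <- check_seed(vol, seed)
  scout <- seeded_component(vol$values >= scout_threshold, seed)
  suvmax <- if (any(scout)) max(vol$values[scout]) else vol$values[seed[1], seed[2], seed[3]]
  thr <- fraction * suvmax
  m <- seeded_component(vol$values >= thr, seed)
  attr(m, "threshold") <- thr
  m
}

#' Background-adapted 50%-of-SUVpeak segmentation (A50peak)
#'
#' Iterative contrast-adapted thresholding. Starting from the seeded
#' component at an absolute SUV `scout_threshold` (falling back to the seed
#' voxel alone when that component is empty), each iteration computes the
#' current mask's SUVpeak (1 mL sphere, see [suv_peak]) and the local
#' background `BG` as the mean SUV in the `shell_mm` shell around the mask,
#' sets the threshold `T = BG + 0.5 * (SUVpeak - BG)`, and regrows the seeded
#' component at `T`. Iteration stops when `T` changes by less than `tol` SUV
#' or after `max_iter` iterations; in the latter case the last mask is
#' returned with `converged = FALSE`.
#'
#' @inheritParams fixed_threshold_mask
#' @param contrast fraction of the peak-background contrast added to the
#'   background (0.5 for the 50% variant).
#' @param shell_mm background shell distance bounds from the mask surface, mm.
#' @param tol convergence tolerance on the threshold, SUV.
#' @param max_iter maximum number of iterations.
#' @param scout_threshold absolute SUV used for the initial mask.
#' @return logical mask with attributes `threshold` (final SUV threshold),
#'   `converged` (logical) and `iterations`.
#' @export
a50peak_mask <- function(vol, seed, contrast = 0.5, shell_mm = c(10, 15),
                         tol = 0.01, max_iter = 10L, scout_threshold = 2.5) {
  seed <- check_seed(vol, seed)
  mask <- seeded_component(vol$values >= scout_threshold, seed)
  if (!any(mask)) mask[seed[1], seed[2], seed[3]] <- TRUE
  thr <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    pk <- suv_peak(vol, mask)
    bg <- tryCatch(suvbg_shell(vol, mask, shell_mm = shell_mm)$suvbg,
                   error = function(e) 0)
    new_thr <- bg + contrast * (pk - bg)
    if (!is.na(thr) && abs(new_thr - thr) < tol) {
      # keep the mask grown at `thr`, which it corresponds to exactly
      converged <- TRUE
      break
    }
    thr <- new_thr
    mask <- seeded_component(vol$values >= thr, seed)
    if (!any(mask)) break  # threshold climbed above the seed voxel
  }
  attr(mask, "threshold") <- thr
  attr(mask, "converged") <- converged
  attr(mask, "iterations") <- it
  mask
}

#' Majority-vote fusion of segmentation masks
#'
#' A voxel is retained when it belongs to at least `k` of the input masks;
#' the vote map is then restricted to the 26-connected component containing
#' the seed (empty when the seed voxel is excluded), so the fused mask is a
#' single lesion region like every other operator's output.
#'
#' @param masks list of logical arrays with identical dimensions.
#' @param k minimum number of agreeing masks (2 for MV2, 3 for MV3).
#' @param seed voxel index (i, j, k) of the lesion seed.
#' @return logical mask.
#' @export
majority_vote <- function(masks, k, seed) {
  stopifnot(is.list(masks), length(masks) >= 1L, k >= 1L)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d))
      stop("all masks must share the same dimensions", call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), d)))
  seeded_component(votes >= k, as.integer(seed))
}

#' Apply all six segmentation methods to one seeded lesion
#'
#' Runs SUV2.5, SUV4.0, 41%max and A50peak, then fuses those four into MV2
#' and MV3. Returns exactly one record per method with the applied threshold,
#' the metabolic tumour volume (MTV, mL) and the mask SUVmax. Empty masks are
#' legal outputs (MTV 0), corresponding to a failed/incomplete delineation.
#'
#' @inheritParams fixed_threshold_mask
#' @param a50_args optional list of arguments forwarded to [a50peak_mask].
#' @return an object of class `lesion_segmentation`: list with `results`
#'   (data frame: method, threshold_used, n_voxels, mtv_ml, suvmax, converged)
#'   and `masks` (named list of logical arrays), plus `seed` and `spacing`.
#' @export
segment_all <- function(vol, seed, a50_args = list()) {
  seed <- check_seed(vol, seed)
  m25 <- fixed_threshold_mask(vol, seed, 2.5)
  m40 <- fixed_threshold_mask(vol, seed, 4.0)
  m41 <- relative41_mask(vol, seed)
  ma50 <- do.call(a50peak_mask, c(list(vol = vol, seed = seed), a50_args))
  four <- list(m25, m40, m41, ma50)
  mv2 <- majority_vote(four, 2L, seed)
  mv3 <- majority_vote(four, 3L, seed)
  masks <- list(m25, m40, m41, ma50, mv2, mv3)
  names(masks) <- pet_methods()
  thr <- c(2.5, 4.0, attr(m41, "threshold"), attr(ma50, "threshold"), NA, NA)
  res <- data.frame(
    method = pet_methods(),
    threshold_used = thr,
    n_voxels = vapply(masks, sum, numeric(1)),
    mtv_ml = vapply(masks, mtv, numeric(1), spacing = vol$spacing),
    suvmax = vapply(masks, function(m)
      if (any(m)) max(vol$values[m]) else NA_real_, numeric(1)),
    converged = c(TRUE, TRUE, TRUE, isTRUE(attr(ma50, "converged")), TRUE, TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(results = res, masks = masks, seed = seed,
                 spacing = vol$spacing),
            class = "lesion_segmentation")
}

#' @export
print.lesion_segmentation <- function(x, ...) {
  cat("Six-method lesion segmentation at seed (",
      paste(x$seed, collapse = ", "), ")\n", sep = "")
  print(x$results, digits = 4)
  invisible(x)
}
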