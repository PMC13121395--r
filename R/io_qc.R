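#' Scan quality control against EANM-style criteria
#'
#' A scan passes QC when the liver SUVmean lies in \[1.3, 3.0\], plasma
#' glucose is below 11 mmol/L, the total image activity is within 50–80%
#' of the injected activity, and the DICOM data are complete. All violated
#' criteria are enumerated.
#'
#' @param liver_suvmean liver SUVmean of the scan.
#' @param plasma_glucose plasma glucose, mmol/L.
#' @param activity_fraction total image activity as a fraction of injected
#'   activity.
#' @param dicom_complete logical; whether the DICOM data are complete.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty on pass).
#' @export
qc_check <- function(liver_suvmean, plasma_glucose, activity_fraction,
                     dicom_complete) {
  args <- list(liver_suvmean = liver_suvmean, plasma_glucose = plasma_glucose,
               activity_fraction = activity_fraction,
               dicom_complete = dicom_complete)
  for (nm in names(args))
    if (is.null(args[[nm]]) || length(args[[nm]]) != 1L || is.na(args[[nm]]))
      stop("missing QC field: ", nm, call. = FALSE)
  reasons <- character()
  if (liver_suvmean < 1.3 || liver_suvmean > 3.0)
    reasons <- c(reasons, sprintf("liver SUVmean %.2f outside [1.3, 3.0]", liver_suvmean))
  if (plasma_glucose >= 11)
    reasons <- c(reasons, sprintf("plasma glucose %.1f mmol/L >= 11", plasma_glucose))
  if (activity_fraction < 0.50 || activity_fraction > 0.80)
    reasons <- c(reasons, sprintf("image activity fraction %.2f outside [0.50, 0.80]",
                                  activity_fraction))
  if (!isTRUE(dicom_complete))
    reasons <- c(reasons, "incomplete DICOM data")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Read and write SUV volumes and masks as NIfTI-1
#'
#' Volumes are stored as double-precision NIfTI-1 with the voxel spacing in
#' the header, so a write/read round trip is bit-identical. Masks are stored
#' as unsigned 8-bit label maps with values in \{0, 1\}, aligned to their
#' volume.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_suv_volume`: an [suv_volume]; `read_mask`: a logical array
#'   with the spacing attached as attribute `spacing`.
#' @export
read_suv_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D NIfTI volume", call. = FALSE)
  suv_volume(array(as.numeric(vals), dim(vals)),
             spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_suv_volume
#' @param vol an [suv_volume].
#' @export
write_suv_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$values)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname read_suv_volume
#' @param mask logical 3-D array.
#' @param vol an [suv_volume] the mask is aligned to (provides spacing and
#'   a shape check).
#' @export
write_mask <- function(mask, path, vol) {
  stopifnot(inherits(vol, "suv_volume"))
  if (!identical(dim(mask), dim(vol$values)))
    stop("mask and volume dimensions differ", call. = FALSE)
  lab <- array(as.integer(mask), dim(mask))
  img <- RNifti::asNifti(lab)
  img <- RNifti::`pixdim<-`(img, vol$spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname read_suv_volume
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (!all(vals %in% c(0, 1)))
    stop("mask file contains labels other than {0, 1}", call. = FALSE)
  m <- array(vals == 1, dim(vals))
  attr(m, "spacing") <- RNifti::pixdim(img)[1:3]
  m
}

# required columns of the rated lesion table CSV schema (version 1)
rating_table_columns <- function() {
  c("lesion_id", "scan_id", "timepoint", "location",
    "suvpeak", "suvbg", "tbrpeak",
    paste0("rating_", pet_methods()), paste0("mtv_", pet_methods()))
}

#' Read / write rated lesion tables as CSV
#'
#' The CSV schema carries one row per lesion with identifier, timepoint,
#' location, the three uptake features and per-method rating and MTV
#' columns; missing required columns raise an error naming them.
#'
#' @param path CSV file path.
#' @return data frame with the validated schema.
#' @export
read_rating_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(rating_table_columns(), names(tab))
  if (length(missing_cols))
    stop("rating table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

#' @rdname read_rating_table
#' @param table data frame to write.
#' @export
write_rating_table <- function(table, path) {
  missing_cols <- setdiff(rating_table_columns(), names(table))
  if (length(missing_cols))
    stop("rating table is missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
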