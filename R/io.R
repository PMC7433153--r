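# NIfTI and JSON interchange. Volumes and masks travel as .nii.gz with the
# voxel spacing in the header; cohort tables as CSV; configs and region
# manifests as JSON.

#' Write a volume or mask as NIfTI
#'
#' Masks are stored as 0/1 integers; spacing goes into the header pixdim.
#'
#' @param vol 3-D numeric or logical array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing) {
  spacing <- check_spacing(spacing)
  if (is.logical(vol)) vol <- array(as.integer(vol), dim(vol))
  img <- RNifti::asNifti(vol, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @param as_mask_ if `TRUE`, binarize (`> 0`) to a logical mask.
#' @return list `vol` (array), `spacing` (mm).
#' @export
read_volume <- function(path, as_mask_ = FALSE) {
  if (!file.exists(path))
    stop_dectpeel(paste0("cannot read volume: ", path), "dectpeel_io_error")
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  vol <- array(as.numeric(img), dim(img))
  if (as_mask_) vol <- array(vol > 0, dim(vol))
  list(vol = vol, spacing = spacing)
}

#' Write the masks of a region set as NIfTI files plus a JSON manifest
#'
#' @param rs a `region_set`.
#' @param prefix path prefix; each region goes to `<prefix><name>.nii.gz`.
#' @return manifest path, invisibly.
#' @export
write_region_set <- function(rs, prefix) {
  masks <- region_masks(rs)
  files <- character()
  for (nm in names(masks)) {
    f <- paste0(prefix, nm, ".nii.gz")
    write_volume(masks[[nm]], f, rs$spacing)
    files[nm] <- f
  }
  manifest <- list(thickness_mm = rs$config$thickness_mm,
                   spacing = rs$spacing, files = as.list(files),
                   empty_regions = rs$empty_regions)
  mpath <- paste0(prefix, "regions.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Serialize a spec or config to JSON
#'
#' @param x a `phantom_spec`, `cohort_spec` or `pipeline_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

#' Write a cohort table as CSV
#'
#' Header contract: `patient_id`, `mvi`, then one column per feature;
#' missing cells stay empty (never imputed).
#'
#' @param table cohort data.frame.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table CSV
#'
#' @param path CSV written by [write_cohort_csv()] or following the same
#'   header contract.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop_dectpeel(paste0("cannot read cohort table: ", path),
                  "dectpeel_io_error")
  read.csv(path, stringsAsFactors = FALSE)
}
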