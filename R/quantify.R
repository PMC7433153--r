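# Per-region dual-energy statistics: mean mixed-energy attenuation, total
# and vital iodine concentration, NIC, and parenchyma-normalized attenuation
# ratios; plus assembly of per-patient feature rows.
#
# Conventions (recorded in output metadata): "total" iodine concentration is
# the mean concentration (mg/mL) over all region voxels; "vital" is the mean
# over voxels whose concentration exceeds the vital threshold (enhancing
# subset), 0 if none; NIC = vital / aortic concentration; attenuation ratios
# are region mean over parenchyma mean, so hyper-enhancing regions score
# above 1.

#' Per-region dual-energy statistics
#'
#' @param region logical mask (possibly empty: statistics come back missing).
#' @param mixed 3-D mixed-energy HU array.
#' @param iodine 3-D iodine map (mg/mL), non-negative.
#' @param aorta_ic aortic iodine concentration (mg/mL), > 0.
#' @param parenchyma logical mask of normal liver parenchyma for the
#'   attenuation ratio (may be `NULL` or empty: ratio reported missing).
#' @param vital_threshold mg/mL above which a voxel counts as enhancing
#'   (default 0.5).
#' @param region_name label carried into the output.
#' @param spacing voxel spacing in mm; enables the iodine mass readout.
#' @return object of class `region_stats`: `region_name`, `n_voxels`,
#'   `mean_hu`, `total_ic`, `vital_ic`, `nic`,
#'   `lesion_to_parenchyma_ratio`, `iodine_mass_mg` (when spacing given),
#'   `missing`.
#' @export
region_stats <- function(region, mixed, iodine, aorta_ic, parenchyma = NULL,
                         vital_threshold = 0.5, region_name = "region",
                         spacing = NULL) {
  check_same_grid(region, mixed, iodine)
  if (!is.numeric(aorta_ic) || aorta_ic <= 0)
    stop_dectpeel("aortic iodine concentration must be > 0",
                  "dectpeel_normalization_error")
  region <- as_mask(region)
  n <- sum(region)
  if (n == 0L) {
    return(structure(list(region_name = region_name, n_voxels = 0L,
                          mean_hu = NA_real_, total_ic = NA_real_,
                          vital_ic = NA_real_, nic = NA_real_,
                          lesion_to_parenchyma_ratio = NA_real_,
                          iodine_mass_mg = NA_real_, missing = TRUE),
                     class = "region_stats"))
  }
  vals_hu <- mixed[region]
  vals_io <- iodine[region]
  total_ic <- mean(vals_io)
  vital <- vals_io[vals_io > vital_threshold]
  vital_ic <- if (length(vital)) mean(vital) else 0
  ratio <- NA_real_
  if (!is.null(parenchyma)) {
    check_same_grid(region, parenchyma)
    parenchyma <- as_mask(parenchyma)
    if (any(parenchyma)) ratio <- mean(vals_hu) / mean(mixed[parenchyma])
  }
  mass <- if (is.null(spacing)) NA_real_ else
    n * prod(check_spacing(spacing)) / 1000 * total_ic
  structure(list(region_name = region_name, n_voxels = n,
                 mean_hu = mean(vals_hu), total_ic = total_ic,
                 vital_ic = vital_ic, nic = vital_ic / aorta_ic,
                 lesion_to_parenchyma_ratio = ratio,
                 iodine_mass_mg = mass, missing = FALSE),
            class = "region_stats")
}

#' @export
print.region_stats <- function(x, ...) {
  if (x$missing) {
    cat(sprintf("<region_stats> %s: empty (missing)\n", x$region_name))
  } else {
    cat(sprintf(
      "<region_stats> %s: %d vox, mean %.1f HU, IC %.3f (vital %.3f) mg/mL, NIC %.3f\n",
      x$region_name, x$n_voxels, x$mean_hu, x$total_ic, x$vital_ic, x$nic))
  }
  invisible(x)
}

#' Normal-parenchyma mask
#'
#' Liver minus tumor, minus every peritumoral layer, minus exclusions: the
#' reference tissue for attenuation normalization.
#'
#' @param liver,tumor logical masks; `outer_layers` a list of masks (may be
#'   empty); `exclusion` optional mask.
#' @return logical mask; errors if the result is empty.
#' @export
parenchyma_mask <- function(liver, tumor, outer_layers = list(),
                            exclusion = NULL) {
  check_same_grid(liver, tumor)
  out <- as_mask(liver) & !as_mask(tumor)
  for (m in outer_layers) {
    check_same_grid(liver, m)
    out <- out & !as_mask(m)
  }
  if (!is.null(exclusion)) {
    check_same_grid(liver, exclusion)
    out <- out & !as_mask(exclusion)
  }
  if (!any(out))
    stop_dectpeel("parenchyma mask is empty (tumor occupies whole liver?)",
                  "dectpeel_parenchyma_undefined")
  out
}

#' Assemble a per-patient feature row
#'
#' Flattens `region_stats` objects collected at one or more layer
#' thicknesses into a single wide row with deterministic column naming
#' `<metric>_<region>_<thickness>mm` (e.g. `nic_outer1_2mm`). Missing
#' regions yield `NA` cells; the row is always retained.
#'
#' @param stats_by_thickness named list, one element per thickness (names
#'   like `"2"`), each a list of `region_stats`.
#' @param patient_id identifier for the row.
#' @param mvi 0/1 label (may be `NA` when unknown).
#' @param qualitative optional named list of 0/1 reader scores (e.g.
#'   `peritumoral_enhancement`, `nonsmooth_margin`); omitted when `NULL`.
#' @return one-row `data.frame`.
#' @export
patient_features <- function(stats_by_thickness, patient_id, mvi = NA,
                             qualitative = NULL) {
  row <- list(patient_id = patient_id, mvi = mvi)
  for (th in names(stats_by_thickness)) {
    stats <- stats_by_thickness[[th]]
    nms <- vapply(stats, function(s) s$region_name, character(1))
    if (anyDuplicated(nms))
      stop_dectpeel("duplicate region names in one thickness",
                    "dectpeel_validation_error")
    for (s in stats) {
      suffix <- paste0(s$region_name, "_", th, "mm")
      row[[paste0("nic_", suffix)]] <- s$nic
      row[[paste0("mean_hu_", suffix)]] <- s$mean_hu
      row[[paste0("total_ic_", suffix)]] <- s$total_ic
      row[[paste0("ratio_", suffix)]] <- s$lesion_to_parenchyma_ratio
    }
  }
  if (!is.null(qualitative)) row <- c(row, qualitative)
  as.data.frame(row, stringsAsFactors = FALSE)
}
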