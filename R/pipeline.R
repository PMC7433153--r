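# End-to-end per-case and per-cohort drivers tying decomposition,
# segmentation, peeling and quantification together.

#' Pipeline configuration
#'
#' @param calib a [calibration_matrix()].
#' @param thicknesses_mm layer thicknesses to analyze (default `c(2, 4)`).
#' @param vital_threshold mg/mL enhancing-voxel threshold.
#' @param blend_weight mixed-image low-kV fraction.
#' @param seg_params list passed to [segment_tumor()].
#' @param liver_params list passed to [segment_liver()].
#' @param n_outer,n_inner layers per side.
#' @param seed integer, recorded in manifests.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(calib = calibration_matrix(),
                            thicknesses_mm = c(2, 4),
                            vital_threshold = 0.5, blend_weight = 0.6,
                            seg_params = list(), liver_params = list(),
                            n_outer = 2L, n_inner = 2L, seed = 1L) {
  if (any(thicknesses_mm <= 0))
    stop_dectpeel("thicknesses must be > 0", "dectpeel_validation_error")
  structure(list(calib = calib, thicknesses_mm = thicknesses_mm,
                 vital_threshold = vital_threshold,
                 blend_weight = blend_weight, seg_params = seg_params,
                 liver_params = liver_params, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full per-case pipeline
#'
#' Decompose, segment (or accept supplied masks), peel at every configured
#' thickness, quantify, and return one feature row. The aorta mask must be
#' supplied (clinically an ROI drawn in the aorta); the liver mask is
#' segmented from the mixed image when not supplied.
#'
#' @param study a [de_study()].
#' @param aorta_mask logical aortic blood-pool mask.
#' @param line a [diameter_line()] seeding tumor segmentation; ignored when
#'   `tumor_mask` is supplied.
#' @param tumor_mask,liver_mask optional externally supplied masks.
#' @param exclusion_mask optional vessel/extrahepatic exclusion mask.
#' @param config a [pipeline_config()].
#' @param patient_id,mvi row metadata.
#' @param qualitative optional named list of 0/1 reader scores.
#' @return list `features` (one-row data.frame), `regions` (list of
#'   `region_set` by thickness), `segmentation`, `aorta_ic`, `maps`.
#' @export
run_case <- function(study, aorta_mask, line = NULL, tumor_mask = NULL,
                     liver_mask = NULL, exclusion_mask = NULL,
                     config = pipeline_config(), patient_id = "case",
                     mvi = NA, qualitative = NULL) {
  stopifnot(inherits(study, "de_study"), inherits(config, "pipeline_config"))
  maps <- decompose_iodine(study, config$calib,
                           blend_weight = config$blend_weight)
  a_ic <- aorta_iodine(maps$iodine, aorta_mask)

  seg <- NULL
  if (is.null(tumor_mask)) {
    if (is.null(line))
      stop_dectpeel("supply either a diameter line or a tumor mask",
                    "dectpeel_validation_error")
    seg <- segment_tumor(maps$mixed, line, study$spacing, config$seg_params)
    tumor_mask <- seg$mask
  } else {
    tumor_mask <- as_mask(tumor_mask)
  }
  liver_mask <- segment_liver(maps$mixed, study$spacing,
                              config$liver_params,
                              supplied_mask = liver_mask)

  regions <- list()
  stats_by_th <- list()
  for (th in config$thicknesses_mm) {
    rs <- peel_layers(tumor_mask, liver_mask, exclusion_mask,
                      study$spacing,
                      layer_config(th, config$n_outer, config$n_inner))
    regions[[as.character(th)]] <- rs
    paren <- parenchyma_mask(liver_mask, tumor_mask, rs$outer,
                             exclusion_mask)
    masks <- region_masks(rs)
    stats_by_th[[as.character(th)]] <- lapply(names(masks), function(nm) {
      region_stats(masks[[nm]], maps$mixed, maps$iodine, a_ic, paren,
                   config$vital_threshold, region_name = nm,
                   spacing = study$spacing)
    })
  }
  features <- patient_features(stats_by_th, patient_id, mvi, qualitative)
  list(features = features, regions = regions, segmentation = seg,
       aorta_ic = a_ic, maps = maps)
}

#' Run cohort statistics over assembled case rows
#'
#' @param rows data.frame of per-patient feature rows (e.g. stacked
#'   [run_case()] outputs or a [generate_cohort()] table).
#' @param config list forwarded to [cohort_report()].
#' @return a `cohort_report`.
#' @export
run_cohort <- function(rows, config = list()) {
  if (!is.data.frame(rows) || nrow(rows) < 4L)
    stop_dectpeel("need at least 2 patients per class",
                  "dectpeel_validation_error")
  counts <- table(rows$mvi)
  if (length(counts) < 2L || any(counts < 2L))
    stop_dectpeel("need at least 2 patients per class",
                  "dectpeel_validation_error")
  cohort_report(rows, config)
}
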