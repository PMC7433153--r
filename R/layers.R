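# Distance-banded peritumoral ("outer") and intratumoral ("inner") layers,
# and the five analysis VOIs built from them. Distances are Euclidean, in
# mm, from each voxel center to the tumor boundary under a half-voxel
# interface convention (the boundary lies midway between adjacent inside
# and outside voxel centers; see boundary_distance), with anisotropic
# spacing respected. Bands are half-open (low, high] so that consecutive
# layers are disjoint and exhaustive. Outer layers are clipped to liver
# minus exclusions; inner layers live inside the tumor and are never
# clipped.

#' Layer-peeling configuration
#'
#' @param thickness_mm band thickness in mm (default 2; the 4-mm variant
#'   probes sensitivity to the peel width).
#' @param n_outer,n_inner number of peritumoral / intratumoral layers.
#' @return object of class `layer_config`.
#' @export
layer_config <- function(thickness_mm = 2, n_outer = 2L, n_inner = 2L) {
  if (thickness_mm <= 0 || n_outer < 0 || n_inner < 0)
    stop_dectpeel("thickness must be > 0 and layer counts >= 0",
                  "dectpeel_validation_error")
  structure(list(thickness_mm = thickness_mm, n_outer = as.integer(n_outer),
                 n_inner = as.integer(n_inner)),
            class = "layer_config")
}

#' Peel peritumoral and intratumoral layers from a tumor mask
#'
#' Outer layer k collects voxels outside the tumor whose distance to the
#' tumor surface lies in `((k-1)*t, k*t]`, intersected with the liver and
#' with exclusions removed; inner layer k collects tumor voxels at the same
#' depth bands measured from the tumor boundary inward. Five VOIs follow by
#' set algebra: `voi_o1 = tumor + outer1`, `voi_o2 = tumor + outer1 +
#' outer2`, `voi_i1 = tumor - inner1`, `voi_i2 = tumor - inner1 - inner2`.
#' Distance is computed from the tumor surface irrespective of exclusions,
#' then clipped. Empty regions are listed in `empty_regions` and propagate
#' as missing values, never zeros.
#'
#' @param tumor,liver logical masks on one grid; `exclusion` optional mask
#'   of large vessels / extrahepatic structures removed from outer layers.
#' @param spacing voxel spacing in mm.
#' @param config a [layer_config()].
#' @return object of class `region_set`: `tumor`, `outer` (list of masks),
#'   `inner` (list), `voi_o1`, `voi_o2`, `voi_i1`, `voi_i2`,
#'   `empty_regions`, plus `spacing` and `config`.
#' @export
peel_layers <- function(tumor, liver, exclusion = NULL, spacing,
                        config = layer_config()) {
  stopifnot(inherits(config, "layer_config"))
  spacing <- check_spacing(spacing)
  tumor <- as_mask(tumor)
  liver <- as_mask(liver)
  check_same_grid(tumor, liver)
  if (is.null(exclusion)) exclusion <- array(FALSE, dim(tumor))
  check_same_grid(tumor, exclusion)
  exclusion <- as_mask(exclusion)
  if (!any(tumor))
    stop_dectpeel("tumor mask is empty", "dectpeel_empty_region")
  if (sum(tumor & !liver) > 0.10 * sum(tumor))
    warning("more than 10% of the tumor lies outside the liver mask")

  t <- config$thickness_mm
  d <- boundary_distance(tumor, spacing)  # to the tumor surface, both sides

  outer <- list()
  if (config$n_outer > 0) {
    for (k in seq_len(config$n_outer)) {
      band <- !tumor & d > (k - 1) * t & d <= k * t
      outer[[k]] <- band & liver & !exclusion
    }
    names(outer) <- paste0("outer", seq_len(config$n_outer))
  }
  inner <- list()
  if (config$n_inner > 0) {
    for (k in seq_len(config$n_inner)) {
      inner[[k]] <- tumor & d > (k - 1) * t & d <= k * t
    }
    names(inner) <- paste0("inner", seq_len(config$n_inner))
  }

  voi_o1 <- if (length(outer) >= 1) tumor | outer[[1]] else NULL
  voi_o2 <- if (length(outer) >= 2) voi_o1 | outer[[2]] else NULL
  voi_i1 <- if (length(inner) >= 1) tumor & !inner[[1]] else NULL
  voi_i2 <- if (length(inner) >= 2) voi_i1 & !inner[[2]] else NULL

  regions <- c(list(tumor = tumor), outer, inner,
               list(voi_o1 = voi_o1, voi_o2 = voi_o2,
                    voi_i1 = voi_i1, voi_i2 = voi_i2))
  regions <- regions[!vapply(regions, is.null, logical(1))]
  empty <- names(regions)[!vapply(regions, any, logical(1))]

  structure(list(tumor = tumor, outer = outer, inner = inner,
                 voi_o1 = voi_o1, voi_o2 = voi_o2, voi_i1 = voi_i1,
                 voi_i2 = voi_i2, empty_regions = empty, spacing = spacing,
                 config = config),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> thickness", x$config$thickness_mm, "mm;",
      length(x$outer), "outer,", length(x$inner), "inner layers\n")
  if (length(x$empty_regions))
    cat("  empty regions:", paste(x$empty_regions, collapse = ", "), "\n")
  invisible(x)
}

#' Flatten a region_set to a named list of masks
#'
#' @param rs a `region_set`.
#' @return named list of logical masks in canonical order (tumor, outer
#'   layers, inner layers, VOIs).
#' @export
region_masks <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  out <- c(list(tumor = rs$tumor), rs$outer, rs$inner,
           list(voi_o1 = rs$voi_o1, voi_o2 = rs$voi_o2,
                voi_i1 = rs$voi_i1, voi_i2 = rs$voi_i2))
  out[!vapply(out, is.null, logical(1))]
}
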