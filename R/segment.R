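# Semiautomatic volumetric tumor segmentation seeded from a user-drawn
# maximal-diameter line, liver segmentation for phantoms, mask editing and
# morphometrics. The region-growing algorithm is deliberately simple and
# fully parameterized: seed statistics in a small sphere at the line
# midpoint, connected-threshold growth within mean +/- k*SD, confined to a
# bounding ellipsoid scaled from the drawn line, then a one-voxel
# morphological closing and largest-connected-component selection.

#' User-drawn maximal-diameter line
#'
#' @param p1,p2 physical endpoint coordinates in mm (length 3), distinct.
#' @param plane acquisition plane the line was drawn in (metadata only).
#' @return object of class `diameter_line` with the endpoints, `midpoint`
#'   and `length_mm`.
#' @export
diameter_line <- function(p1, p2, plane = c("axial", "coronal", "sagittal")) {
  plane <- match.arg(plane)
  if (length(p1) != 3L || length(p2) != 3L || all(p1 == p2))
    stop_dectpeel("line endpoints must be two distinct mm coordinates",
                  "dectpeel_validation_error")
  structure(list(p1 = as.numeric(p1), p2 = as.numeric(p2), plane = plane,
                 midpoint = (as.numeric(p1) + as.numeric(p2)) / 2,
                 length_mm = sqrt(sum((p1 - p2)^2))),
            class = "diameter_line")
}

mm_to_voxel <- function(p, spacing) as.integer(round(p / spacing)) + 1L

#' Segment a tumor from a diameter line
#'
#' @param mixed 3-D mixed-energy HU array.
#' @param line a [diameter_line()]; both endpoints must lie inside the image.
#' @param spacing voxel spacing in mm.
#' @param params list of tuning parameters: `seed_radius_mm` (sphere for the
#'   seed statistics, default 3), `k_sd` (admission half-width in seed SDs,
#'   default 2.5), `min_halfwidth_hu` (floor on the admission half-width so
#'   uniform seeds still grow, default 5 HU), `ellipsoid_scale` (bounding
#'   sphere diameter as a multiple of the line length, default 1.5).
#' @return object of class `segmentation_result`: `mask`, `volume_ml`,
#'   `max_diameter_mm`, `line_length_mm`, `edited`, `low_contrast`.
#' @export
segment_tumor <- function(mixed, line, spacing, params = list()) {
  stopifnot(inherits(line, "diameter_line"))
  spacing <- check_spacing(spacing)
  p <- list(seed_radius_mm = 3, k_sd = 2.5, min_halfwidth_hu = 5,
            ellipsoid_scale = 1.5)
  p[names(params)] <- params
  d <- dim(mixed)
  extent <- (d - 1) * spacing
  for (pt in list(line$p1, line$p2))
    if (any(pt < 0) || any(pt > extent))
      stop_dectpeel("line endpoint outside the image extent",
                    "dectpeel_validation_error")

  g <- voxel_grid_mm(d, spacing)
  mid <- line$midpoint
  r2 <- (g$x - mid[1])^2 + (g$y - mid[2])^2 + (g$z - mid[3])^2
  seed_sphere <- r2 <= p$seed_radius_mm^2
  vals <- mixed[seed_sphere]
  if (length(vals) == 0L)
    stop_dectpeel("seed sphere contains no voxels",
                  "dectpeel_segmentation_failed")
  mu <- mean(vals)
  halfwidth <- max(p$k_sd * sd(vals), p$min_halfwidth_hu, na.rm = TRUE)

  # bounding ellipsoid (sphere in world space): diameter = scale * line length
  radius <- p$ellipsoid_scale * line$length_mm / 2
  allowed <- r2 <= radius^2

  seed_vox <- mm_to_voxel(mid, spacing)
  seed_idx <- (seed_vox[3] - 1) * d[1] * d[2] + (seed_vox[2] - 1) * d[1] +
    seed_vox[1] - 1
  grown <- array(cpp_region_grow(as.vector(mixed), as.vector(allowed), d,
                                 seed_idx, mu - halfwidth, mu + halfwidth),
                 d)
  if (!any(grown))
    stop_dectpeel("seed statistics admit no voxels",
                  "dectpeel_segmentation_failed")
  low_contrast <- sum(grown) / sum(allowed) > 0.95

  mask <- largest_component(binary_close6(grown))
  met <- mask_metrics(mask, spacing)
  structure(list(mask = mask, volume_ml = met$volume_ml,
                 max_diameter_mm = met$max_diameter_mm,
                 line_length_mm = line$length_mm, edited = FALSE,
                 low_contrast = low_contrast),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d voxels, %.2f mL, max diameter %.1f mm%s%s\n",
              sum(x$mask), x$volume_ml, x$max_diameter_mm,
              if (x$edited) ", edited" else "",
              if (isTRUE(x$low_contrast)) ", LOW CONTRAST" else ""))
  invisible(x)
}

#' Manually edit a segmentation mask
#'
#' Applies reader edits as set algebra: `(mask | add) & !remove`.
#'
#' @param mask,add,remove logical arrays on one grid; `add`/`remove` may be
#'   `NULL` for no edit.
#' @return edited logical mask with attribute `edited = TRUE`.
#' @export
edit_mask <- function(mask, add = NULL, remove = NULL) {
  d <- dim(mask)
  out <- as_mask(mask)
  if (!is.null(add)) {
    check_same_grid(mask, add)
    out <- out | as_mask(add)
  }
  if (!is.null(remove)) {
    check_same_grid(mask, remove)
    out <- out & !as_mask(remove)
  }
  attr(out, "edited") <- TRUE
  out
}

#' Segment the liver on a phantom-grade image
#'
#' Threshold band, largest 6-connected component, interior hole filling
#' (the hyper-enhancing tumor is a "hole" in the parenchymal band). A
#' supplied mask is passed through verbatim, mirroring workflows where the
#' liver outline comes from elsewhere.
#'
#' @param mixed 3-D mixed-energy HU array.
#' @param spacing voxel spacing in mm.
#' @param params list: `hu_range` (parenchymal admission band, default
#'   `c(30, 120)` HU).
#' @param supplied_mask optional externally provided liver mask, returned
#'   unchanged.
#' @return logical liver mask.
#' @export
segment_liver <- function(mixed, spacing, params = list(),
                          supplied_mask = NULL) {
  if (!is.null(supplied_mask)) {
    check_same_grid(mixed, supplied_mask)
    return(as_mask(supplied_mask))
  }
  p <- list(hu_range = c(30, 120))
  p[names(params)] <- params
  band <- mixed >= p$hu_range[1] & mixed <= p$hu_range[2]
  if (!any(band))
    stop_dectpeel("no voxels in the parenchymal HU band",
                  "dectpeel_segmentation_failed")
  out <- fill_holes(largest_component(band))
  if (!any(out))
    stop_dectpeel("liver segmentation produced an empty mask",
                  "dectpeel_segmentation_failed")
  out
}

#' Mask morphometrics
#'
#' Volume as voxel count times voxel volume; maximal diameter as the 3-D
#' Feret diameter, i.e. the largest pairwise Euclidean distance between
#' surface-voxel centers (surface voxels are mask voxels with at least one
#' 6-neighbor outside the mask; the maximizing pair necessarily lies on the
#' convex hull of these points).
#'
#' @param mask logical 3-D array, non-empty.
#' @param spacing voxel spacing in mm.
#' @return list `volume_ml`, `max_diameter_mm`, `n_voxels`.
#' @export
mask_metrics <- function(mask, spacing) {
  spacing <- check_spacing(spacing)
  mask <- as_mask(mask)
  n <- sum(mask)
  if (n == 0L)
    stop_dectpeel("mask is empty", "dectpeel_empty_region")
  vol <- n * prod(spacing) / 1000
  surface <- mask & !binary_erode6(mask)
  pts <- mask_coords_mm(surface, spacing)
  diam <- if (nrow(pts) < 2L) 0 else cpp_max_pairwise(pts)
  list(volume_ml = vol, max_diameter_mm = diam, n_voxels = n)
}
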