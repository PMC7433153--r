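# Synthetic dual-energy CT phantom: a liver ellipsoid containing a
# hyper-enhancing tumor, an aortic cylinder, and (for MVI-positive cases) a
# peritumoral enhancing rim. The forward model is linear in iodine:
#   HU_low  = base_hu + s_low  * c + noise
#   HU_high = base_hu + s_high * c + noise
# with c the ground-truth iodine concentration map (mg/mL) and independent
# Gaussian HU noise per energy channel.

#' Calibration matrix for two-material decomposition
#'
#' Iodine sensitivities in HU per mg/mL at the low (80 kV) and high
#' (tin-filtered 150 kV) energies. Iodine attenuates more strongly at low
#' energy, so `s_low > s_high > 0` is required.
#'
#' @param s_low,s_high HU increase per mg/mL iodine at low / high energy.
#' @return object of class `calibration_matrix`.
#' @export
calibration_matrix <- function(s_low = 48, s_high = 15) {
  if (!(is.numeric(s_low) && is.numeric(s_high) && s_low > s_high &&
        s_high > 0))
    stop_dectpeel("calibration requires s_low > s_high > 0",
                  "dectpeel_validation_error")
  structure(list(s_low = s_low, s_high = s_high),
            class = "calibration_matrix")
}

#' Specification of a synthetic dual-energy liver phantom
#'
#' Defaults place a spherical tumor at the center of a liver ellipsoid with
#' an aortic cylinder running alongside. Baseline (non-contrast) HU and
#' iodine concentrations per tissue are chosen so that, against a 10 mg/mL
#' aortic blood pool, normal parenchyma has NIC 0.07 -- the scale reported
#' for peritumoral layers of tumors without microvascular invasion.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param spacing mm per voxel, length 3.
#' @param liver_center,liver_axes ellipsoid center and semi-axes (mm).
#' @param tumor_center,tumor_radius_mm tumor sphere center (mm) and radius.
#' @param lobulated if `TRUE`, modulate the tumor radius with smooth angular
#'   bumps of amplitude `bump_amp_mm` (a non-smooth margin variant).
#' @param bump_amp_mm bump amplitude in mm for the lobulated variant.
#' @param aorta_center_xy,aorta_radius_mm aortic cylinder (axis along z).
#' @param tissue_hu named list: baseline HU for `background`, `liver`,
#'   `tumor`, `aorta` without any iodine.
#' @param iodine_mgml named list: iodine concentration (mg/mL) for `liver`,
#'   `tumor`, `aorta`, and `rim_increment` added on top of liver parenchyma
#'   inside the rim.
#' @param rim_present,rim_thickness_mm peritumoral enhancing rim (the imaging
#'   correlate of microvascular invasion in this phantom family).
#' @param noise_sd additive Gaussian noise SD in HU, independent per channel.
#' @param seed integer RNG seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 64L),
                         spacing = c(1, 1, 1),
                         liver_center = c(26, 32, 32),
                         liver_axes = c(20, 18, 26),
                         tumor_center = c(26, 32, 32),
                         tumor_radius_mm = 9,
                         lobulated = FALSE,
                         bump_amp_mm = 1.5,
                         aorta_center_xy = c(54, 32),
                         aorta_radius_mm = 5,
                         tissue_hu = list(background = -100, liver = 60,
                                          tumor = 50, aorta = 40),
                         iodine_mgml = list(liver = 0.7, tumor = 2.5,
                                            aorta = 10, rim_increment = 0.5),
                         rim_present = FALSE,
                         rim_thickness_mm = 2,
                         noise_sd = 0,
                         seed = 1L) {
  spacing <- check_spacing(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 8))
    stop_dectpeel("grid_shape must be 3 integers >= 8",
                  "dectpeel_validation_error")
  if (tumor_radius_mm <= 0 || aorta_radius_mm <= 0 || any(liver_axes <= 0))
    stop_dectpeel("geometry radii must be positive",
                  "dectpeel_validation_error")
  conc <- unlist(iodine_mgml)
  if (any(conc < 0))
    stop_dectpeel("iodine concentrations must be >= 0",
                  "dectpeel_validation_error")
  if (rim_present && rim_thickness_mm <= 0)
    stop_dectpeel("rim thickness must be > 0 when the rim is present",
                  "dectpeel_validation_error")
  if (noise_sd < 0)
    stop_dectpeel("noise_sd must be >= 0", "dectpeel_validation_error")
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 liver_center = liver_center, liver_axes = liver_axes,
                 tumor_center = tumor_center,
                 tumor_radius_mm = tumor_radius_mm,
                 lobulated = lobulated, bump_amp_mm = bump_amp_mm,
                 aorta_center_xy = aorta_center_xy,
                 aorta_radius_mm = aorta_radius_mm,
                 tissue_hu = tissue_hu, iodine_mgml = iodine_mgml,
                 rim_present = rim_present,
                 rim_thickness_mm = rim_thickness_mm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# world coordinates (mm) of every voxel center, one array per axis
voxel_grid_mm <- function(grid_shape, spacing) {
  xs <- (seq_len(grid_shape[1]) - 1) * spacing[1]
  ys <- (seq_len(grid_shape[2]) - 1) * spacing[2]
  zs <- (seq_len(grid_shape[3]) - 1) * spacing[3]
  list(x = array(rep(xs, times = grid_shape[2] * grid_shape[3]), grid_shape),
       y = array(rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
                 grid_shape),
       z = array(rep(zs, each = grid_shape[1] * grid_shape[2]), grid_shape))
}

#' Generate a synthetic dual-energy study with ground truth
#'
#' Rasterizes the phantom geometry, builds the ground-truth iodine map, and
#' applies the linear two-material forward model at both energies. With
#' `noise_sd = 0` the output is a deterministic function of the spec;
#' otherwise independent Gaussian HU noise is added per channel,
#' reproducibly under the spec seed.
#'
#' @param spec a [phantom_spec()].
#' @param calib a [calibration_matrix()].
#' @return list with `study` (a `de_study`: `low_kv`, `high_kv`, `spacing`),
#'   `masks` (logical arrays `tumor`, `liver`, `aorta`), and `iodine_truth`
#'   (mg/mL array).
#' @export
generate_phantom <- function(spec, calib = calibration_matrix()) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(calib,
                                                     "calibration_matrix"))
  g <- voxel_grid_mm(spec$grid_shape, spec$spacing)

  liver <- ((g$x - spec$liver_center[1]) / spec$liver_axes[1])^2 +
    ((g$y - spec$liver_center[2]) / spec$liver_axes[2])^2 +
    ((g$z - spec$liver_center[3]) / spec$liver_axes[3])^2 <= 1

  dxt <- g$x - spec$tumor_center[1]
  dyt <- g$y - spec$tumor_center[2]
  dzt <- g$z - spec$tumor_center[3]
  r <- sqrt(dxt^2 + dyt^2 + dzt^2)
  if (spec$lobulated) {
    # smooth low-order angular modulation of the radius: a deterministic
    # non-smooth-margin variant
    theta <- acos(ifelse(r > 0, dzt / pmax(r, 1e-9), 1))
    phi <- atan2(dyt, dxt)
    rloc <- spec$tumor_radius_mm +
      spec$bump_amp_mm * sin(3 * theta)^2 * cos(2 * phi)
    tumor <- r <= rloc
  } else {
    tumor <- r <= spec$tumor_radius_mm
  }

  if (any(tumor & !liver))
    stop_dectpeel("tumor is not strictly inside the liver",
                  "dectpeel_geometry_error")

  aorta <- (g$x - spec$aorta_center_xy[1])^2 +
    (g$y - spec$aorta_center_xy[2])^2 <= spec$aorta_radius_mm^2
  if (any(aorta & liver))
    stop_dectpeel("aorta intersects the liver ellipsoid",
                  "dectpeel_geometry_error")

  hu <- spec$tissue_hu
  base <- array(hu$background, spec$grid_shape)
  base[liver] <- hu$liver
  base[tumor] <- hu$tumor
  base[aorta] <- hu$aorta

  io <- spec$iodine_mgml
  conc <- array(0, spec$grid_shape)
  conc[liver] <- io$liver
  conc[tumor] <- io$tumor
  conc[aorta] <- io$aorta
  if (spec$rim_present) {
    d_out <- boundary_distance(tumor, spec$spacing)
    rim <- !tumor & liver & d_out <= spec$rim_thickness_mm
    conc[rim] <- io$liver + io$rim_increment
  }

  low <- base + calib$s_low * conc
  high <- base + calib$s_high * conc
  if (spec$noise_sd > 0) {
    withr::with_seed(spec$seed, {
      low <- low + array(rnorm(length(low), 0, spec$noise_sd),
                         spec$grid_shape)
      high <- high + array(rnorm(length(high), 0, spec$noise_sd),
                           spec$grid_shape)
    })
  }

  list(study = de_study(low, high, spec$spacing),
       masks = list(tumor = tumor, liver = liver, aorta = aorta),
       iodine_truth = conc)
}
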