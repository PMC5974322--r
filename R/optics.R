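# Deterministic arithmetic of the spinning-disk / camera geometry.

#' Spinning-disk optics configuration
#'
#' Bundles the geometry of a spinning-disk confocal setup: a Nipkow disk
#' rotating at `disk_rpm` whose pinhole pattern sweeps the full field in a
#' fraction `scan_fraction` of one rotation, pinholes spaced
#' `pinhole_spacing_um_on_disk` micrometres apart on the disk, demagnified
#' onto the sample by `total_magnification`, imaged onto a sensor of
#' `sensor_pixels` covering `fov_um` at the sample, with immersion and
#' specimen refractive indices `n_immersion` and `n_specimen`.
#'
#' @param total_magnification total magnification (dimensionless, `> 0`).
#' @param disk_rpm disk rotation speed, revolutions per minute.
#' @param scan_fraction fraction of a rotation per full-field scan, in `(0, 1]`.
#' @param pinhole_spacing_um_on_disk pinhole spacing on the disk, micrometres.
#' @param fov_um field of view at the sample, `c(x, y)` micrometres.
#' @param sensor_pixels sensor size, `c(x, y)` pixels.
#' @param n_immersion,n_specimen refractive indices (air 1.00, water 1.33).
#' @return an object of class `optics_config`.
#' @examples
#' cfg <- optics_config()
#' max_frame_rate(cfg)        # 500 fps
#' focal_plane_spacing(cfg)   # 38.46 um
#' @export
optics_config <- function(total_magnification = 13,
                          disk_rpm = 10000,
                          scan_fraction = 1 / 3,
                          pinhole_spacing_um_on_disk = 500,
                          fov_um = c(1106, 900),
                          sensor_pixels = c(5310, 4320),
                          n_immersion = 1.00,
                          n_specimen = 1.33) {
  assert_scalar_pos(total_magnification, "total_magnification")
  assert_scalar_pos(disk_rpm, "disk_rpm")
  if (!is.numeric(scan_fraction) || scan_fraction <= 0 || scan_fraction > 1) {
    stop("`scan_fraction` must lie in (0, 1]", call. = FALSE)
  }
  assert_scalar_pos(pinhole_spacing_um_on_disk, "pinhole_spacing_um_on_disk")
  stopifnot(length(fov_um) == 2L, all(fov_um > 0),
            length(sensor_pixels) == 2L, all(sensor_pixels >= 1))
  assert_scalar_pos(n_immersion, "n_immersion")
  assert_scalar_pos(n_specimen, "n_specimen")
  structure(
    list(total_magnification = total_magnification, disk_rpm = disk_rpm,
         scan_fraction = scan_fraction,
         pinhole_spacing_um_on_disk = pinhole_spacing_um_on_disk,
         fov_um = as.numeric(fov_um),
         sensor_pixels = as.numeric(sensor_pixels),
         n_immersion = n_immersion, n_specimen = n_specimen),
    class = "optics_config"
  )
}

#' Maximum frame rate of a spinning-disk scan
#'
#' The disk sweeps the full field once per `scan_fraction` of a rotation, so
#' the maximum frame rate is `(disk_rpm / 60) / scan_fraction` frames/s.
#'
#' @param cfg an [optics_config()].
#' @return frames per second.
#' @export
max_frame_rate <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  (cfg$disk_rpm / 60) / cfg$scan_fraction
}

#' Pinhole spacing projected to the focal plane
#'
#' @param cfg an [optics_config()].
#' @return spacing at the sample, micrometres
#'   (`pinhole_spacing_um_on_disk / total_magnification`).
#' @export
focal_plane_spacing <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  cfg$pinhole_spacing_um_on_disk / cfg$total_magnification
}

#' Pixel size at the sample plane
#'
#' @param fov_um field-of-view extent along one axis, micrometres.
#' @param n_pixels sensor pixels along the same axis (`>= 1`).
#' @return micrometres per pixel (`fov_um / n_pixels`).
#' @examples
#' pixel_size_at_sample(1080, 1024)  # 1.05 um (1K camera)
#' pixel_size_at_sample(1106, 5310)  # 0.21 um (8K camera)
#' @export
pixel_size_at_sample <- function(fov_um, n_pixels) {
  assert_scalar_pos(fov_um, "fov_um")
  if (n_pixels < 1) stop("`n_pixels` must be >= 1", call. = FALSE)
  fov_um / n_pixels
}

#' Refractive-index correction of axial stage displacement
#'
#' When the immersion and specimen refractive indices differ, the focal
#' plane moves `n_specimen / n_immersion` times the stage displacement
#' (1.33-fold for air immersion into water-like tissue).
#'
#' @param stage_displacement_um stage/objective displacement, micrometres
#'   (`>= 0`).
#' @param cfg an [optics_config()].
#' @return corrected focal-plane displacement, micrometres.
#' @export
axial_depth_correction <- function(stage_displacement_um, cfg = optics_config()) {
  stopifnot(inherits(cfg, "optics_config"))
  if (any(stage_displacement_um < 0)) {
    stop("displacement must be >= 0", call. = FALSE)
  }
  stage_displacement_um * cfg$n_specimen / cfg$n_immersion
}

#' Raw data rate of a camera acquisition
#'
#' @param width,height frame size in pixels.
#' @param bytes_per_px bytes per pixel (2 for 16-bit).
#' @param fps frame rate, frames per second.
#' @return bytes per hour (`width * height * bytes_per_px * fps * 3600`).
#' @examples
#' data_rate(5310, 4320, 2, 60) / 1e12  # ~9.91 TB/hour (8K at 60 fps)
#' data_rate(512, 512, 2, 30) / 1e9     # ~56.6 GB/hour (TPLSM)
#' @export
data_rate <- function(width, height, bytes_per_px, fps) {
  for (a in c(width, height, bytes_per_px, fps)) assert_scalar_pos(a, "argument")
  width * height * bytes_per_px * fps * 3600
}

#' Optics summary table
#'
#' Full-precision values of all geometry quantities for a configuration,
#' with the conventionally rounded form (1-2 decimals) alongside.
#'
#' @param cfg an [optics_config()].
#' @param bytes_per_px bytes per pixel for the data-rate row.
#' @param fps frame rate used for the data-rate row (defaults to 60).
#' @return a tibble with columns `quantity`, `value`, `printed`, `unit`.
#' @export
optics_table <- function(cfg = optics_config(), bytes_per_px = 2, fps = 60) {
  vals <- c(
    max_frame_rate_fps = max_frame_rate(cfg),
    focal_plane_spacing_um = focal_plane_spacing(cfg),
    pixel_size_x_um = pixel_size_at_sample(cfg$fov_um[1], cfg$sensor_pixels[1]),
    pixel_size_y_um = pixel_size_at_sample(cfg$fov_um[2], cfg$sensor_pixels[2]),
    axial_correction_factor = cfg$n_specimen / cfg$n_immersion,
    data_rate_tb_per_hour = data_rate(cfg$sensor_pixels[1], cfg$sensor_pixels[2],
                                      bytes_per_px, fps) / 1e12
  )
  tibble::tibble(
    quantity = names(vals),
    value = unname(vals),
    printed = vapply(unname(vals), format_printed, ""),
    unit = c("fps", "um", "um/px", "um/px", "", "TB/h")
  )
}

# Round the way the field prints these quantities: 1-2 significant decimals.
format_printed <- function(x) {
  if (x >= 100) format(round(x)) else format(signif(x, 3))
}

## ---- survey arithmetic of a field of extracted ROIs -----------------------

#' ROI density of an imaging field
#'
#' @param n_rois number of ROIs detected.
#' @param field_um field size, `c(x, y)` micrometres.
#' @return ROIs per square millimetre.
#' @examples
#' roi_density_per_mm2(291, c(213, 213))  # 6414 ROIs/mm^2
#' @export
roi_density_per_mm2 <- function(n_rois, field_um) {
  stopifnot(length(field_um) == 2L, all(field_um > 0), n_rois >= 0)
  n_rois / (prod(field_um) / 1e6)
}

#' Detection ratio between two imaging modalities
#'
#' @param value,reference a quantity (density, rate, ...) under the modality
#'   of interest and under the reference modality.
#' @return percentage `100 * value / reference`.
#' @examples
#' detection_ratio(6414, 19540)  # ~33% ROI-density ratio
#' detection_ratio(32.7, 58.3)   # ~56% spike-event ratio
#' @export
detection_ratio <- function(value, reference) {
  assert_scalar_pos(reference, "reference")
  100 * value / reference
}

#' Volume-corrected bouton detection fraction
#'
#' A thicker optical section samples proportionally more boutons; dividing
#' the raw detection ratio by the axial-extent ratio of the two modalities
#' gives the fraction of boutons detected per unit sampled volume.
#'
#' @param ratio_pct raw detection ratio in percent.
#' @param axial_ratio ratio of axial FWHMs (sampled-thickness ratio),
#'   e.g. ~8.5/~3.2 = about 3.
#' @return percentage.
#' @examples
#' volume_corrected_fraction(detection_ratio(6414, 19540), 3)  # ~11%
#' @export
volume_corrected_fraction <- function(ratio_pct, axial_ratio) {
  assert_scalar_pos(axial_ratio, "axial_ratio")
  ratio_pct / axial_ratio
}

#' Linear bouton density along an arbor
#'
#' @param n_boutons bouton (peak) count along the traced path.
#' @param path_length_mm traced path length in millimetres.
#' @return boutons per millimetre.
#' @examples
#' boutons_per_mm(144, 2.10)  # 68.6/mm
#' @export
boutons_per_mm <- function(n_boutons, path_length_mm) {
  assert_scalar_pos(path_length_mm, "path_length_mm")
  n_boutons / path_length_mm
}
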