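#' Physical calibration of a mask stack
#'
#' A voxel geometry ties pixel indices to physical micrometres. Within a slice,
#' `x` runs along columns and `z` along rows; the stack axis `y` runs along the
#' slice index (the sectioning direction). Pixel centres sit at
#' `(index - 1) * pitch`, and slice `i` sits at `y = (i - 1) * slice_spacing`.
#'
#' The slice spacing is always derived as
#' `section_thickness * subsampling_factor`: the defaults describe 3 um
#' physical sections of which every 5th is segmented, giving 15 um between
#' consecutive masks. Subsampling is a calibration parameter, not a resampling
#' operation.
#'
#' @param pixel_pitch_x Pixel pitch along columns, um. Default 1.48.
#' @param pixel_pitch_z Pixel pitch along rows, um. Default 1.48.
#' @param section_thickness Physical section thickness, um. Default 3.
#' @param subsampling_factor Every how-many-th section is segmented (>= 1).
#'   Default 5.
#' @return An object of class `voxel_geometry`: a list with the four inputs
#'   plus the derived `slice_spacing` (um).
#' @examples
#' g <- voxel_geometry()
#' g$slice_spacing  # 15
#' @export
voxel_geometry <- function(pixel_pitch_x = 1.48, pixel_pitch_z = 1.48,
                           section_thickness = 3, subsampling_factor = 5L) {
  stopifnot(pixel_pitch_x > 0, pixel_pitch_z > 0, section_thickness > 0)
  subsampling_factor <- as.integer(subsampling_factor)
  if (is.na(subsampling_factor) || subsampling_factor < 1L)
    stop("'subsampling_factor' must be an integer >= 1")
  structure(list(
    pixel_pitch_x = pixel_pitch_x,
    pixel_pitch_z = pixel_pitch_z,
    section_thickness = section_thickness,
    subsampling_factor = subsampling_factor,
    slice_spacing = section_thickness * subsampling_factor
  ), class = "voxel_geometry")
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "voxel_geometry: %.4g x %.4g um pixels, %g um sections x %d => %g um slice spacing\n",
    x$pixel_pitch_x, x$pixel_pitch_z, x$section_thickness,
    x$subsampling_factor, x$slice_spacing))
  invisible(x)
}

is_voxel_geometry <- function(x) inherits(x, "voxel_geometry")

#' Pixel area of one voxel cross-section, um^2
#' @param geometry A [voxel_geometry()].
#' @return Scalar area in um^2.
#' @export
pixel_area <- function(geometry) {
  stopifnot(is_voxel_geometry(geometry))
  geometry$pixel_pitch_x * geometry$pixel_pitch_z
}
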