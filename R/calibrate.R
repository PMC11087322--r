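# Pixel-to-physical calibration from a drawn line of known length.

#' Build a calibration record from a measured line
#'
#' The scale is set by a line drawn on the image between two landmarks of
#' known physical separation (in practice, two consecutive vertical grid
#' lines on the plate): `mm_per_pixel = physical_length_mm / pixel_length`.
#' Pixels are assumed square, so one pixel covers `mm_per_pixel^2` mm².
#'
#' @param pixel_length Length of the drawn line in pixels (> 0).
#' @param physical_length_mm Physical length of the same line in mm (> 0).
#' @param mm_per_pixel Alternatively, give the scale directly.
#' @return A `calibration_record` with fields `mm_per_pixel` and
#'   `area_mm2_per_pixel`.
#' @examples
#' calibrate(pixel_length = 100, physical_length_mm = 10)  # 0.1 mm/px
#' @export
calibrate <- function(pixel_length = NULL, physical_length_mm = NULL,
                      mm_per_pixel = NULL) {
  if (is.null(mm_per_pixel)) {
    if (is.null(pixel_length) || is.null(physical_length_mm))
      stop("calibrate: give pixel_length + physical_length_mm, or mm_per_pixel",
           call. = FALSE)
    if (!is.finite(pixel_length) || pixel_length <= 0 ||
        !is.finite(physical_length_mm) || physical_length_mm <= 0)
      stop("calibrate: lengths must be positive", call. = FALSE)
    mm_per_pixel <- physical_length_mm / pixel_length
  }
  if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("calibrate: mm_per_pixel must be positive", call. = FALSE)
  structure(list(mm_per_pixel = mm_per_pixel,
                 area_mm2_per_pixel = mm_per_pixel^2),
            class = "calibration_record")
}

#' @export
print.calibration_record <- function(x, ...) {
  cat(sprintf("<calibration %.6g mm/px, %.6g mm^2/px>\n",
              x$mm_per_pixel, x$area_mm2_per_pixel))
  invisible(x)
}

#' Convert a pixel count to an area in cm²
#'
#' @param pixel_count Number of pixels in the region (>= 0).
#' @param cal A `calibration_record` from [calibrate()].
#' @return Area in cm²: `pixel_count * area_mm2_per_pixel / 100`.
#' @examples
#' region_area_cm2(10000, calibrate(100, 10))  # 1 cm^2
#' @export
region_area_cm2 <- function(pixel_count, cal) {
  if (!inherits(cal, "calibration_record"))
    stop("region_area_cm2: cal must come from calibrate()", call. = FALSE)
  if (any(!is.finite(pixel_count)) || any(pixel_count < 0))
    stop("region_area_cm2: pixel_count must be >= 0", call. = FALSE)
  pixel_count * cal$area_mm2_per_pixel / 100
}
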