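# sRGB <-> CIELAB conversion (D65 white, 2 degree observer).
#
# The forward path follows the IEC 61966-2-1 sRGB decoding (piecewise gamma),
# the sRGB -> XYZ matrix for the D65 white, and the CIE 1976 L*a*b* formulas.
# The piecewise threshold of f(t) uses the exact rational constants (6/29)^3
# and friends rather than decimal approximations, so the transform is
# bit-reproducible across platforms.

# D65 reference white, 2 degree observer, Y normalised to 100.
.lab_white <- c(X = 95.047, Y = 100.000, Z = 108.883)

# sRGB (linear) -> XYZ, D65. Rows sum to the white point / 100.
.srgb_to_xyz_mat <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), nrow = 3, byrow = TRUE)

.xyz_to_srgb_mat <- solve(.srgb_to_xyz_mat)

#' Construct an 8-bit sRGB image
#'
#' Wraps a numeric array as an `rgb_image`: a height x width x 3 array of
#' integer channel values in \[0, 255\], sRGB-encoded. This is the carrier
#' type for plate photographs throughout the pipeline.
#'
#' @param x Numeric array of dimension `c(height, width, 3)` with values in
#'   \[0, 255\] (integers), or in \[0, 1\] if `scale01 = TRUE`.
#' @param scale01 If `TRUE`, `x` is interpreted as \[0, 1\] doubles (as
#'   returned by [png::readPNG()]) and rescaled to 0..255.
#' @return An `rgb_image` object.
#' @export
rgb_image <- function(x, scale01 = FALSE) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("rgb_image: expected a height x width x 3 array", call. = FALSE)
  if (any(!is.finite(x)))
    stop("rgb_image: non-finite pixel values", call. = FALSE)
  if (scale01) x <- round(x * 255)
  if (any(x < 0 | x > 255) || any(x != round(x)))
    stop("rgb_image: channel values must be integers in [0, 255]", call. = FALSE)
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d, 8-bit sRGB>\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

#' @export
print.lab_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<lab_image %d x %d, L* %.1f..%.1f, b* %.1f..%.1f>\n",
              d[1], d[2], min(x[, , 1]), max(x[, , 1]),
              min(x[, , 3]), max(x[, , 3])))
  invisible(x)
}

# IEC 61966-2-1 electro-optical transfer: encoded [0,1] -> linear [0,1].
.srgb_decode <- function(c) {
  ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
}

# Inverse: linear [0,1] -> encoded [0,1].
.srgb_encode <- function(c) {
  c <- pmax(c, 0)
  ifelse(c <= 0.0031308, 12.92 * c, 1.055 * c^(1 / 2.4) - 0.055)
}

# CIE 1976 f(t); t is X/Xn etc. Threshold (6/29)^3 exactly.
.lab_f <- function(t) {
  d3 <- (6 / 29)^3
  ifelse(t > d3, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_f_inv <- function(f) {
  d <- 6 / 29
  ifelse(f > d, f^3, 3 * d^2 * (f - 4 / 29))
}

#' Convert an sRGB image to CIELAB
#'
#' Converts 8-bit sRGB pixel values to CIELAB coordinates assuming the CIE
#' 1931 2 degree observer and the D65 illuminant, the convention under which
#' blue halo pixels carry negative b*. Dimensions are preserved.
#'
#' @param image An [rgb_image()], or any height x width x 3 array of 8-bit
#'   sRGB values.
#' @return A `lab_image`: height x width x 3 double array whose planes are
#'   L* (0..100), a*, and b*.
#' @examples
#' img <- rgb_image(array(c(255L, 0L, 0L), c(1, 1, 3)))
#' srgb_to_lab(img)[1, 1, ]
#' @export
srgb_to_lab <- function(image) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  d <- dim(image)
  rgb <- matrix(as.numeric(image), ncol = 3L)  # pixels x 3
  xyz <- .srgb_decode(rgb / 255) %*% t(.srgb_to_xyz_mat) * 100
  fx <- .lab_f(xyz[, 1] / .lab_white[["X"]])
  fy <- .lab_f(xyz[, 2] / .lab_white[["Y"]])
  fz <- .lab_f(xyz[, 3] / .lab_white[["Z"]])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  structure(array(lab, dim = d), class = "lab_image")
}

#' Convert CIELAB coordinates to 8-bit sRGB
#'
#' Inverse of [srgb_to_lab()]. Accepts a single `c(L, a, b)` triplet or a
#' `lab_image` array. Out-of-gamut results are clipped to \[0, 255\]; when any
#' pixel was clipped the result carries attribute `clipped = TRUE`.
#'
#' @param color A numeric length-3 vector `c(L, a, b)`, or a `lab_image` /
#'   height x width x 3 array.
#' @return For a triplet, a named integer vector `c(R, G, B)`; for an array,
#'   an [rgb_image()]. Either carries a logical `clipped` attribute.
#' @examples
#' lab_to_srgb(c(100, 0, 0))   # reference white
#' @export
lab_to_srgb <- function(color) {
  single <- is.null(dim(color))
  if (single) {
    if (length(color) != 3L || any(!is.finite(color)))
      stop("lab_to_srgb: expected a finite c(L, a, b) triplet", call. = FALSE)
    lab <- matrix(color, ncol = 3L)
    d <- NULL
  } else {
    d <- dim(color)
    if (length(d) != 3L || d[3] != 3L)
      stop("lab_to_srgb: expected a height x width x 3 array", call. = FALSE)
    lab <- matrix(as.numeric(color), ncol = 3L)
  }
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx) * .lab_white[["X"]],
               .lab_f_inv(fy) * .lab_white[["Y"]],
               .lab_f_inv(fz) * .lab_white[["Z"]]) / 100
  lin <- xyz %*% t(.xyz_to_srgb_mat)
  enc <- .srgb_encode(lin) * 255
  clipped <- any(enc < -0.5 | enc > 255.5) || any(lin < -1e-9)
  v <- pmin(pmax(round(enc), 0), 255)
  if (single) {
    out <- as.integer(v)
    names(out) <- c("R", "G", "B")
  } else {
    out <- rgb_image(array(v, dim = d))
  }
  attr(out, "clipped") <- clipped
  out
}
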