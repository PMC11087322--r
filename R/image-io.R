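#' Read a plate photograph
#'
#' Reads an 8-bit RGB image from PNG, TIFF, or JPEG. An alpha channel, if
#' present, is dropped with a warning; greyscale images are expanded to
#' three identical channels. Pixel data are assumed already sRGB-encoded
#' (no ICC handling), as delivered by consumer cameras.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An [rgb_image()].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      tiff::readTIFF(path)
    },
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] == 4L) {
    warning("alpha channel dropped: ", path, call. = FALSE)
    x <- x[, , 1:3, drop = FALSE]
  }
  if (dim(x)[3] != 3L)
    stop("expected an RGB image, got ", dim(x)[3], " channels: ", path,
         call. = FALSE)
  rgb_image(x, scale01 = TRUE)
}

#' Write an 8-bit image or a binary mask as PNG
#'
#' @param x An [rgb_image()] or a logical matrix (mask, written as
#'   black/white greyscale).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(x, path) {
  if (is.logical(x) && is.matrix(x)) {
    png::writePNG(matrix(as.numeric(x), nrow(x)), path)
  } else {
    if (!inherits(x, "rgb_image")) x <- rgb_image(x)
    png::writePNG(unclass(x) / 255, path)
  }
  invisible(path)
}
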