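#' Read an image as a 0-255 intensity array
#'
#' Reads PNG (via the png package) or JPEG (via the jpeg package, if
#' installed). Grayscale files yield an H x W matrix; color files an
#' H x W x 3 array; an alpha channel, if present, is dropped. Intensities
#' are rescaled from [0, 1] to the integer 0-255 scale used throughout the
#' package (the binarization threshold is defined on that scale).
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return numeric matrix (H x W) or array (H x W x 3) with values in 0-255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image extension '", ext, "' for ", path)
  )
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE] else a <- a[, , 1L]
  }
  round(a * 255)
}

#' Write a 0-255 intensity array as a PNG
#'
#' @param image H x W matrix or H x W x 3 array, values in 0-255.
#' @param path output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.numeric(image))
  if (any(image < 0 | image > 255)) stop("intensities must lie in [0, 255]")
  png::writePNG(image / 255, path)
  invisible(path)
}
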