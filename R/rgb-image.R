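#' 8-bit RGB image container
#'
#' An `rgb_image` is a numeric `height x width x 3` array with intensities in
#' `[0, 255]` and channels ordered red, green, blue. All quality metrics in
#' the package operate on this representation; images are processed at their
#' stored resolution (no internal resizing).
#'
#' @param pixels Numeric array of dimension `height x width x 3`, values in
#'   `[0, 255]`.
#' @return An object of class `rgb_image`.
#' @examples
#' img <- rgb_image(array(128, dim = c(16, 16, 3)))
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be a 3-dimensional array (height x width x 3)", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[3] != 3L) stop("`pixels` must have exactly 3 channels", call. = FALSE)
  if (d[1] < 8L || d[2] < 8L) {
    stop("image must be at least 8 x 8 pixels, got ", d[1], " x ", d[2], call. = FALSE)
  }
  if (!is.numeric(pixels) || anyNA(pixels) || any(!is.finite(pixels))) {
    stop("pixel intensities must be finite numbers", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(unclass(pixels), class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.1f, %.1f]>\n", d[1], d[2], min(x), max(x)))
  invisible(x)
}

is_rgb_image <- function(x) inherits(x, "rgb_image")

assert_rgb_image <- function(x) {
  if (!is_rgb_image(x)) x <- rgb_image(x)
  x
}

#' Read a PNG or JPEG file as an 8-bit RGB image
#'
#' PNG files are read with the \pkg{png} package. JPEG and TIFF files are
#' read through \pkg{EBImage} when it is installed. Grayscale input is
#' replicated across the three channels; an alpha channel is dropped.
#'
#' @param path Path to an image file.
#' @return An [rgb_image].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    px <- aperm(as.array(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    stop("cannot read '", path, "': only PNG is supported without EBImage",
         call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- array(px[, , 1L], dim = c(dim(px)[1:2], 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(round(px * 255))
}

#' Write an 8-bit RGB image to PNG
#'
#' @param image An [rgb_image].
#' @param path Output file path (`.png`).
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  image <- assert_rgb_image(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

# Luma grayscale (Rec. 601 weights), optionally rounded to integer levels.
rgb_to_gray <- function(image, round_levels = FALSE) {
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (round_levels) g <- round(g)
  g
}
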