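#' Grayscale image container
#'
#' All vision routines in denudakit operate on `gray_image` objects: a plain
#' numeric matrix of 8-bit intensities in `[0, 255]` (rows are image rows, so
#' `img[y + 1, x + 1]` addresses the 0-based pixel `(x, y)`), carrying the
#' physical pixel size in micrometres per pixel as an attribute.
#'
#' Pixel coordinates are 0-based, x rightward, y downward, with circle centres
#' and all sub-pixel geometry referred to pixel centres. Micrometre coordinates
#' share the same axes; `um = px * pixel_size_um`.
#'
#' @param data numeric matrix of intensities in `[0, 255]` (values are clipped).
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @return a `gray_image`: the matrix with class and `pixel_size_um` attribute.
#' @examples
#' img <- gray_image(matrix(60, 100, 120), pixel_size_um = 1)
#' dim(img)
#' @export
gray_image <- function(data, pixel_size_um = 1.0) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  data[data < 0] <- 0
  data[data > 255] <- 255
  structure(data,
            pixel_size_um = pixel_size_um,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, %.4g um/px, range [%.1f, %.1f]>\n",
              ncol(x), nrow(x), pixel_size_um(x), min(x), max(x)))
  invisible(x)
}

#' Pixel size of an image
#'
#' @param img a [gray_image].
#' @return micrometres per pixel.
#' @export
pixel_size_um <- function(img) {
  ps <- attr(img, "pixel_size_um")
  if (is.null(ps)) 1.0 else ps
}

# strip class/attributes for handing to EBImage etc.
as_plain_matrix <- function(img) {
  matrix(as.numeric(img), nrow = nrow(img), ncol = ncol(img))
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit grayscale PNG is the native interchange format; TIFF is read when the
#' `tiff` package is available. Multi-channel input is averaged to one channel.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_size_um pixel size to attach (not stored in the file).
#' @return a [gray_image] with intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path, pixel_size_um = 1.0) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 3L) a <- apply(a, c(1L, 2L), mean)
  gray_image(a * 255, pixel_size_um = pixel_size_um)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param img a [gray_image].
#' @param path destination path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  a <- as_plain_matrix(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(a, path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF requires the 'tiff' package")
      }
      tiff::writeTIFF(a, path, bits.per.sample = 8L)
    },
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Crop a rectangular region of interest
#'
#' @param img a [gray_image].
#' @param roi rectangle `c(x, y, w, h)` in 0-based pixel coordinates; must lie
#'   within the image.
#' @return the cropped [gray_image].
#' @export
crop_roi <- function(img, roi) {
  roi <- as.numeric(roi)
  stopifnot(length(roi) == 4L)
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w <= 0 || h <= 0 || x < 0 || y < 0 ||
      x + w > ncol(img) || y + h > nrow(img)) {
    stop("roi must lie within the image")
  }
  gray_image(unclass(img)[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE],
             pixel_size_um = pixel_size_um(img))
}

#' Translate an image by an integer pixel offset
#'
#' Shifts content by `(dx, dy)`; uncovered pixels are filled with `fill`.
#' Used by the translation-equivariance checks of the detectors.
#'
#' @param img a [gray_image].
#' @param dx,dy integer shifts in pixels (content moves right/down for
#'   positive values).
#' @param fill intensity for uncovered pixels.
#' @return the translated [gray_image].
#' @export
translate_image <- function(img, dx, dy, fill = 0) {
  dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
  h <- nrow(img); w <- ncol(img)
  out <- matrix(fill, h, w)
  sx <- max(0L, dx); sy <- max(0L, dy)          # dest start (0-based)
  ox <- max(0L, -dx); oy <- max(0L, -dy)        # source start
  cw <- w - abs(dx); ch <- h - abs(dy)
  if (cw > 0 && ch > 0) {
    out[(sy + 1):(sy + ch), (sx + 1):(sx + cw)] <-
      unclass(img)[(oy + 1):(oy + ch), (ox + 1):(ox + cw)]
  }
  gray_image(out, pixel_size_um = pixel_size_um(img))
}
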