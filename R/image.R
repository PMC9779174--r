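#' 8-bit RGB image container
#'
#' Wraps a `height x width x 3` integer array of 8-bit channel intensities
#' (R, G, B in `[0, 255]`) as the raw input to the vegetation-index pipeline.
#'
#' @param x A numeric array of dimension `c(height, width, 3)` with integral
#'   values in `[0, 255]`, or an object coercible to one.
#' @return An object of class `rgb_image`: the integer array with channels
#'   ordered R, G, B along the third dimension.
#' @examples
#' img <- rgb_image(array(c(10, 200, 30), dim = c(1, 1, 3)))
#' dim(img)
#' @export
rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  x <- as.array(x)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an rgb_image needs a height x width x 3 array, got dimensions ",
         paste(dim(x), collapse = " x "))
  if (anyNA(x) || !all(is.finite(x)))
    stop("rgb_image intensities must be finite")
  if (any(x < 0 | x > 255))
    stop("rgb_image intensities must lie in [0, 255]")
  if (any(x != round(x)))
    stop("rgb_image intensities must be integers (8-bit DNs)")
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 x 8-bit channels\n", d[1], d[2]))
  invisible(x)
}

#' Read an RGB image from file
#'
#' Reads an 8-bit PNG, TIFF or JPEG file into an [rgb_image()]. An alpha
#' channel, if present, is dropped with a warning; greyscale images are
#' replicated to three channels.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return An `rgb_image`.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package")
      jpeg::readJPEG(path)
    },
    stop("unsupported image format '.", ext, "' (use PNG, TIFF or JPEG)")
  )
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  nch <- dim(arr)[3]
  if (nch == 2L || nch == 4L) {
    warning("ignoring alpha channel in ", basename(path))
    arr <- arr[, , seq_len(nch - 1L), drop = FALSE]
    nch <- dim(arr)[3]
  }
  if (nch == 1L) arr <- array(rep(arr, 3L), dim = c(dim(arr)[1:2], 3L))
  rgb_image(round(arr * 255))
}

#' Write a binary vegetation mask as a 1-bit style PNG
#'
#' Vegetation pixels (1) are written as white (255), non-vegetation (0) as
#' black; [read_mask_png()] restores the 0/1 matrix losslessly.
#'
#' @param mask Binary matrix (0/1 or logical).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1]
  as_mask(arr >= 0.5)
}

# coerce a logical/0-1 matrix to the internal integer mask form
as_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1L
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0L, 1L)))
    stop("a vegetation mask may only contain 0 (non-vegetation) and 1 (vegetation)")
  storage.mode(mask) <- "integer"
  mask
}

channel <- function(image, i) {
  matrix(as.numeric(image[, , i]), dim(image)[1], dim(image)[2])
}
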