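#' Read a raster image (PNG, JPEG or TIFF)
#'
#' Decodes to the package's in-memory convention: a numeric matrix
#' (grayscale) or `M x N x 3` array (RGB) of 8-bit intensities in
#' `[0, 255]`. An alpha channel, if present, is dropped.
#'
#' @param path Image file; format inferred from the extension.
#' @return Grayscale matrix or RGB array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("the 'jpeg' package is required to read ", path)
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read ", path)
      tiff::readTIFF(path)
    },
    stop("unsupported image format '", ext, "': ", path))
  px <- round(raw * 255)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 1) px <- px[, , 1]
    else if (dim(px)[3] >= 3) px <- px[, , 1:3]
    else stop("unsupported channel count in ", path)
  }
  px
}

#' Write an image as lossless 8-bit PNG
#'
#' @param image Grayscale matrix or RGB array on the 0-255 scale.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  check_image(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}
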