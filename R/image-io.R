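#' Read an 8-bit grayscale image (PNG or TIFF)
#'
#' Color inputs are converted to grayscale by channel averaging.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return Integer matrix in `[0, 255]` (rows = y, columns = x).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3]), drop = FALSE], c(1, 2), mean)
  clip8(arr * 255)
}

#' Write an 8-bit grayscale image (PNG or TIFF)
#'
#' @param img integer matrix in `[0, 255]`.
#' @param path destination; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(img, path) {
  assert_gray(img)
  ext <- tolower(tools::file_ext(path))
  arr <- img / 255
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format: ", ext, call. = FALSE))
  invisible(path)
}
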