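# Mask I/O: single-channel TIFF/PNG, nonzero = foreground.

#' Read / write a binary mask
#'
#' Reads a single-channel TIFF or PNG (first channel of multi-channel
#' images) and binarizes it at zero. Image files store rows top-to-bottom;
#' they are returned as matrices indexed `mask[row, col]`.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_mask` returns a logical matrix; `write_mask` returns `path`
#'   invisibly.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                phreno_stop("InvalidParams", "unsupported mask format '%s'",
                            ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img != 0
}

#' @param mask logical or 0/1 matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  ext <- tolower(tools::file_ext(path))
  img <- (mask != 0) * 1
  switch(ext,
         tif = , tiff = tiff::writeTIFF(img, path),
         png = png::writePNG(img, path),
         phreno_stop("InvalidParams", "unsupported mask format '%s'", ext))
  invisible(path)
}
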