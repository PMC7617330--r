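#' Read / write grayscale images as 16-bit TIFF
#'
#' Convenience wrappers for exchanging image fixtures (12-bit data in a
#' 16-bit container). Values are stored as `counts / 65535` and restored on
#' read. Requires the `tiff` package.
#'
#' @param img numeric matrix of counts in [0, 65535].
#' @param path file path.
#' @return `read_image_tiff` returns a numeric matrix of counts.
#' @export
write_image_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  if (min(img) < 0 || max(img) > 65535)
    stop("counts must lie in [0, 65535]", call. = FALSE)
  tiff::writeTIFF(img / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF i/o", call. = FALSE)
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * 65535
}
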