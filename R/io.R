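# Multi-page TIFF I/O for (z, y, x) volumes and masks. Intensities in
# this package are dimensionless and near [0, 1]; float TIFF storage
# clamps to [0, 1], so volumes are divided by a scale factor on write
# (returned invisibly) and multiplied back on read.

#' Read and write volumes as multi-page TIFF
#'
#' @param volume (z, y, x) numeric array.
#' @param path file path.
#' @param scale divisor applied before writing; defaults to
#'   `max(1, max(volume))` so values fit the float [0, 1] payload.
#' @return `write_volume_tiff()` returns `scale` invisibly;
#'   `read_volume_tiff()` returns the (z, y, x) array times `scale`.
#' @export
write_volume_tiff <- function(volume, path, scale = NULL) {
  stopifnot(length(dim(volume)) == 3)
  if (is.null(scale)) scale <- max(1, max(volume))
  pages <- lapply(seq_len(dim(volume)[1]),
                  function(iz) pmax(volume[iz, , ] / scale, 0))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(scale)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- array(0, c(length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2]))
  for (iz in seq_along(pages)) out[iz, , ] <- pages[[iz]]
  out * scale
}

#' @rdname write_volume_tiff
#' @param mask logical (z, y, x) array; stored as 8-bit.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(length(dim(mask)) == 3)
  pages <- lapply(seq_len(dim(mask)[1]),
                  function(iz) (mask[iz, , ]) * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_mask_tiff <- function(path) {
  read_volume_tiff(path) > 0.5
}
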