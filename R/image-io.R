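#' Read a plant image
#'
#' Reads a PNG or JPEG file into the package's native representation: an
#' `H x W x 3` numeric array with channel values in `[0, 255]`, rows being
#' image rows (y) and columns image columns (x). Greyscale images are
#' expanded to three identical channels; an alpha channel is dropped.
#'
#' @param path Path to a PNG/JPEG file.
#' @return Numeric `H x W x 3` array in `[0, 255]`.
#' @export
read_plant_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)     # dim = (x, y[, c])
  if (length(dim(dat)) == 2L) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  }
  if (dim(dat)[3L] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  out <- aperm(dat, c(2L, 1L, 3L)) * 255
  out
}

#' Write a binary mask as a PNG file
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix (`mask[y, x]`).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write an RGB image array as a PNG file
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

# internal: logical matrix -> EBImage Image (x, y) and back
as_ebimage <- function(mask) EBImage::Image(t(mask * 1))
from_ebimage <- function(img) t(EBImage::imageData(img)) > 0.5
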