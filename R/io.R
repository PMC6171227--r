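#' Read a single-channel grayscale image
#'
#' Supports 8/16-bit (or float) grayscale TIFF and grayscale PNG. The pixel
#' size is supplied by the caller (it is an acquisition parameter, not read
#' from file metadata). TIFF intensities are returned on their native scale;
#' PNG values are scaled to 0..255.
#'
#' @param path file path (`.tif`, `.tiff` or `.png`).
#' @param pixel_size_um micrometers per pixel of the stored image.
#' @return An [image2d].
#' @export
read_gray_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path) * 255
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 1) {
      px <- px[, , 1]
    } else {
      stop("multi-channel (RGB/RGBA) input is not supported; ",
           "supply a single-channel grayscale image")
    }
  }
  image2d(px, pixel_size_um)
}

#' Write / read a label map as 16-bit TIFF
#'
#' Round-trips losslessly for up to 65535 labels.
#'
#' @param x a [label_map].
#' @param path output path.
#' @export
write_label_map <- function(x, path) {
  stopifnot(is_label_map(x))
  mx <- max(x$labels)
  if (mx > 65535) stop("label map has ", mx, " labels; 16-bit TIFF allows ",
                       "at most 65535")
  tiff::writeTIFF(x$labels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_label_map
#' @param pixel_size_um micrometers per pixel of the stored map.
#' @export
read_label_map <- function(path, pixel_size_um) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(v)) == 3) stop("expected a single-page single-channel TIFF")
  label_map(round(v), pixel_size_um)
}

#' Write / read probability maps as a 3-page 32-bit float TIFF
#'
#' Page order is nuclei, cytoplasm, background.
#'
#' @param x a [probmaps] object.
#' @param path output path.
#' @export
write_probmaps <- function(x, path) {
  stopifnot(inherits(x, "probmaps"))
  tiff::writeTIFF(list(x$p_n, x$p_c, x$p_b), path, bits.per.sample = 32,
                  compression = "none")
  invisible(path)
}

#' @rdname write_probmaps
#' @param pixel_size_um micrometers per pixel of the stored maps.
#' @export
read_probmaps <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3) stop("expected a 3-page TIFF (nuclei, cytoplasm, ",
                               "background); got ", length(pages), " page(s)")
  probmaps(pages[[1]], pages[[2]], pages[[3]], pixel_size_um)
}

#' Write an intensity image as 16-bit grayscale TIFF
#'
#' Values are rounded to integers and must fit 0..65535 (the native range
#' of 16-bit microscopy cameras).
#'
#' @param img an [image2d].
#' @param path output path.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is_image2d(img))
  v <- round(img$pixels)
  if (max(v) > 65535)
    stop("intensities exceed the 16-bit range (max ", max(v), ")")
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}
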