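#' White top-hat illumination correction
#'
#' Subtracts the morphological opening of the image with a flat square
#' structuring element, suppressing any background structure wider than the
#' kernel (slowly varying illumination in particular) while features narrower
#' than the kernel are retained. Applied identically before training and
#' before inference. The default 200-pixel kernel is defined at native
#' resolution, so the correction runs before any magnification resampling.
#'
#' @param img an [image2d].
#' @param kernel_px side of the square structuring element in pixels
#'   (default 200); must be at least 3 and no larger than both image
#'   dimensions.
#' @return An [image2d] of the same shape and pixel size; values are
#'   nonnegative and never exceed the input (an opening is anti-extensive).
#' @examples
#' img <- image2d(matrix(50, 64, 64), 0.65)
#' out <- tophat_correct(img, kernel_px = 16)
#' all(out$pixels == 0)  # opening of a constant is the constant
#' @export
tophat_correct <- function(img, kernel_px = 200) {
  stopifnot(is_image2d(img))
  kernel_px <- as.integer(kernel_px)
  if (kernel_px < 3) stop("`kernel_px` must be at least 3")
  d <- dim(img$pixels)
  if (kernel_px > d[1] && kernel_px > d[2])
    stop("top-hat kernel (", kernel_px, " px) is larger than both image ",
         "dimensions (", d[1], " x ", d[2], "); choose a smaller kernel")
  opened <- cpp_box_dilate_reflected(cpp_box_erode(img$pixels, kernel_px),
                                     kernel_px)
  image2d(img$pixels - opened, img$pixel_size_um)
}

#' Resample an image to the reference magnification
#'
#' Downsamples to the stated target pixel size (0.65 um, i.e. roughly 10x)
#' by area averaging when the scale ratio is an integer and by anti-aliased
#' interpolation otherwise. Upsampling is never performed: images already at
#' or coarser than the target pass through unchanged (with a warning when
#' coarser). Pixel sizes within 5% of the target count as already there.
#'
#' @param img an [image2d].
#' @param target_pixel_size_um target pixel size in micrometers
#'   (default 0.65).
#' @return An [image2d] at (approximately) the target pixel size.
#' @export
resample_to_reference <- function(img, target_pixel_size_um = 0.65) {
  stopifnot(is_image2d(img))
  ps <- img$pixel_size_um
  if (abs(ps - target_pixel_size_um) / target_pixel_size_um <= 0.05)
    return(img)
  if (ps > target_pixel_size_um) {
    warning("pixel size (", ps, " um) is coarser than the target (",
            target_pixel_size_um, " um); upsampling is never performed, ",
            "returning the image unchanged")
    return(img)
  }
  f <- target_pixel_size_um / ps
  d <- dim(img$pixels)
  newd <- pmax(1L, as.integer(round(d * ps / target_pixel_size_um)))
  if (abs(f - round(f)) < 1e-9 && all(d %% round(f) == 0)) {
    k <- as.integer(round(f))
    px <- block_mean(img$pixels, k)
  } else {
    px <- as.matrix(EBImage::resize(img$pixels, w = newd[1], h = newd[2],
                                    antialias = TRUE))
    px[px < 0] <- 0
  }
  image2d(px, target_pixel_size_um)
}

# exact area averaging over k x k blocks (dims divisible by k)
block_mean <- function(m, k) {
  d <- dim(m)
  a <- array(m, c(k, d[1] %/% k, k, d[2] %/% k))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}
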