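#' Single-channel 2-D intensity image with physical pixel size
#'
#' The basic container for a grayscale microscopy frame: a numeric matrix of
#' nonnegative intensities plus the isotropic physical edge length of one
#' pixel in micrometers. All downstream parameters quoted in micrometers
#' (blob scales, the h-minima depth, expected cell areas) are converted to
#' pixels through `pixel_size_um`.
#'
#' @param pixels numeric matrix of finite, nonnegative intensities.
#' @param pixel_size_um positive scalar, micrometers per pixel (isotropic).
#' @return An object of class `image2d`.
#' @examples
#' img <- image2d(matrix(runif(64, 0, 100), 8, 8), pixel_size_um = 0.65)
#' dim(img)
#' @export
image2d <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite everywhere")
  if (any(pixels < 0))
    stop("`pixels` must be nonnegative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "image2d")
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image2d> %d x %d px @ %.4g um/px, range [%.4g, %.4g]\n",
              d[1], d[2], x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_image2d <- function(x) inherits(x, "image2d")

as_image2d <- function(x, pixel_size_um) {
  if (is_image2d(x)) x else image2d(x, pixel_size_um)
}

#' Integer-labeled segmentation map
#'
#' A 2-D grid of nonnegative integers: 0 is background, each positive value
#' labels one 8-connected object. Used for nucleus seeds, segmented cells and
#' ground-truth objects.
#'
#' @param labels integer (or whole-number numeric) matrix, values >= 0.
#' @param pixel_size_um positive scalar, micrometers per pixel.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size_um) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be nonnegative integers")
  storage.mode(labels) <- "integer"
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_map")
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d px @ %.4g um/px, %d object(s)\n",
              d[1], d[2], x$pixel_size_um, n_objects(x)))
  invisible(x)
}

is_label_map <- function(x) inherits(x, "label_map")

#' Number of distinct objects in a label map
#' @param x a `label_map` (or integer matrix).
#' @return integer count of distinct positive labels.
#' @export
n_objects <- function(x) {
  m <- if (is_label_map(x)) x$labels else x
  length(setdiff(unique(as.vector(m)), 0L))
}

label_matrix <- function(x) if (is_label_map(x)) x$labels else x

#' Label the 8-connected components of a binary mask
#'
#' @param mask logical or 0/1 matrix.
#' @param pixel_size_um micrometers per pixel for the returned map.
#' @return A `label_map` with one label per 8-connected foreground component.
#' @export
label_components <- function(mask, pixel_size_um = 1) {
  m <- mask
  storage.mode(m) <- "integer"
  label_map(cpp_label8(m), pixel_size_um)
}

#' Per-pixel class probability maps
#'
#' The three real-valued maps (nuclei, cytoplasm, background) produced by the
#' pixel classifier; every value lies in \[0, 1\].
#'
#' @param p_n,p_c,p_b numeric matrices of identical shape with values in
#'   \[0, 1\].
#' @param pixel_size_um micrometers per pixel.
#' @return An object of class `probmaps`.
#' @export
probmaps <- function(p_n, p_c, p_b, pixel_size_um) {
  for (m in list(p_n, p_c, p_b)) {
    if (!is.matrix(m) || !identical(dim(m), dim(p_n)))
      stop("probability maps must be matrices of one shape")
    if (any(m < 0) || any(m > 1)) stop("probabilities must lie in [0, 1]")
  }
  structure(list(p_n = p_n, p_c = p_c, p_b = p_b,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "probmaps")
}

#' @export
print.probmaps <- function(x, ...) {
  d <- dim(x$p_n)
  cat(sprintf("<probmaps> %d x %d px, channels n/c/b, means %.3f/%.3f/%.3f\n",
              d[1], d[2], mean(x$p_n), mean(x$p_c), mean(x$p_b)))
  invisible(x)
}
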