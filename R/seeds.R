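#' Parameters of the nucleus-seed detector
#'
#' @param log_sigmas_um Gaussian scales of the multi-scale blob detector, in
#'   micrometers; strictly increasing, all positive. The default covers
#'   nucleus radii of 2-8 um in four logarithmic steps.
#' @param otsu_levels number of thresholds of the multi-level Otsu step
#'   (default 5).
#' @param sensitivity detection sensitivity in \[0, 100\]; it selects which
#'   of the `otsu_levels` ascending thresholds binarizes the blob response,
#'   via `index = clamp(round(sensitivity * otsu_levels / 100), 1,
#'   otsu_levels)`. The default 60 picks the third threshold of five.
#' @param h_um depth parameter of the extended h-minima transform used to
#'   split touching nuclei, in micrometers (default 3).
#' @return A list of class `seed_params`.
#' @export
seed_params <- function(log_sigmas_um = exp(seq(log(2), log(8),
                                                length.out = 4)),
                        otsu_levels = 5, sensitivity = 60, h_um = 3) {
  if (length(log_sigmas_um) < 1 || any(log_sigmas_um <= 0) ||
      is.unsorted(log_sigmas_um, strictly = TRUE))
    stop("`log_sigmas_um` must be strictly increasing and positive")
  if (sensitivity < 0 || sensitivity > 100)
    stop("`sensitivity` must lie in [0, 100]")
  if (h_um <= 0) stop("`h_um` must be positive")
  if (otsu_levels < 1) stop("`otsu_levels` must be at least 1")
  structure(list(log_sigmas_um = log_sigmas_um,
                 otsu_levels = as.integer(otsu_levels),
                 sensitivity = sensitivity, h_um = h_um),
            class = "seed_params")
}

#' Multi-scale Laplacian-of-Gaussian blob response
#'
#' Enhances bright blob-like regions (the nuclei in the nuclei probability
#' map) by taking, per pixel, the maximum over scales of the
#' scale-normalized negative Laplacian-of-Gaussian response
#' `-sigma^2 * Laplacian(G_sigma * p)`. For a Gaussian blob the normalized
#' response peaks at the matching scale, so a grid of sigmas detects nuclei
#' of different sizes. Negative responses are clamped to zero.
#'
#' @param p_n nuclei probability map (matrix, values in \[0, 1\]).
#' @param pixel_size_um micrometers per pixel, used to convert the sigma
#'   grid to pixels.
#' @param params a [seed_params].
#' @param return_stack also return the per-scale responses (3-D array) as
#'   attribute `stack` (default FALSE).
#' @return Nonnegative response matrix; attribute `sigmas_px` holds the
#'   pixel-unit scale grid.
#' @export
multiscale_log <- function(p_n, pixel_size_um, params = seed_params(),
                           return_stack = FALSE) {
  if (length(params$log_sigmas_um) == 0) stop("empty sigma list")
  if (any(p_n < 0) || any(p_n > 1))
    stop("`p_n` must be a probability map in [0, 1]")
  sig_px <- params$log_sigmas_um / pixel_size_um
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  resp <- matrix(-Inf, nrow(p_n), ncol(p_n))
  stack <- if (return_stack)
    array(0, c(nrow(p_n), ncol(p_n), length(sig_px))) else NULL
  maxr <- min(dim(p_n)) - (min(dim(p_n)) + 1) %% 2  # largest odd <= min dim
  for (i in seq_along(sig_px)) {
    g <- as.matrix(EBImage::gblur(p_n, sigma = sig_px[i],
                                  radius = min(2 * ceiling(3 * sig_px[i]) + 1,
                                               maxr),
                                  boundary = "replicate"))
    r <- -sig_px[i]^2 *
      as.matrix(EBImage::filter2(g, lap, boundary = "replicate"))
    if (return_stack) stack[, , i] <- r
    resp <- pmax(resp, r)
  }
  resp[resp < 0] <- 0
  attr(resp, "sigmas_px") <- sig_px
  if (return_stack) attr(resp, "stack") <- stack
  resp
}

#' Binarize a blob response at a sensitivity-selected Otsu threshold
#'
#' Computes `otsu_levels` ascending multi-level Otsu thresholds of the
#' response and keeps everything at or above the sensitivity-selected one
#' (all blob classes above the chosen threshold count as nuclei), merging
#' all detections into a single binary nuclear mask. Higher sensitivity
#' selects a higher threshold index, i.e. a more conservative mask; masks
#' are therefore nested as sensitivity grows.
#'
#' @param response matrix from [multiscale_log()].
#' @param params a [seed_params].
#' @return Logical matrix (the binary nuclear mask); attribute `threshold`
#'   holds the selected threshold, `index` its 1-based rank.
#' @export
binarize_sensitivity <- function(response, params = seed_params()) {
  L <- params$otsu_levels
  th <- multilevel_otsu(response, L)
  idx <- min(max(round(params$sensitivity * L / 100), 1), L)
  mask <- response >= th[idx]
  attr(mask, "threshold") <- th[idx]
  attr(mask, "index") <- idx
  mask
}

#' Split a binary nuclear mask into individual nucleus seeds
#'
#' Shape-based watershed separation of touching nuclei: (1) the Euclidean
#' distance transform of the mask is computed; (2) its negation is the
#' watershed surface, so nucleus centers are deep minima; (3) an extended
#' h-minima transform suppresses minima shallower than `h` (in micrometers,
#' converted to pixels) and the surviving regional minima become markers;
#' (4) a seeded watershed restricted to the mask grows one label per marker.
#'
#' @param mask logical/binary matrix.
#' @param pixel_size_um micrometers per pixel.
#' @param params a [seed_params] (uses `h_um`).
#' @return A [label_map] of nucleus seeds; an empty mask yields an empty map.
#' @export
split_nuclei <- function(mask, pixel_size_um, params = seed_params()) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0))
    return(label_map(matrix(0L, nrow(m), ncol(m)), pixel_size_um))
  D <- as.matrix(EBImage::distmap(m))
  surf <- -D
  h_px <- params$h_um / pixel_size_um
  markers <- cpp_hminima_markers(surf, h_px, m)
  label_map(cpp_watershed(surf, markers, m), pixel_size_um)
}

#' Detect nucleus seeds from a nuclei probability map
#'
#' The full seed-detection chain: multi-scale LoG blob enhancement,
#' sensitivity-selected multi-level Otsu binarization, and watershed
#' splitting of touching nuclei.
#'
#' @param p_n nuclei probability map.
#' @param pixel_size_um micrometers per pixel.
#' @param params a [seed_params].
#' @return A [label_map] of individually labeled nucleus seeds.
#' @export
detect_seeds <- function(p_n, pixel_size_um, params = seed_params()) {
  resp <- multiscale_log(p_n, pixel_size_um, params)
  if (max(resp) == 0)
    return(label_map(matrix(0L, nrow(p_n), ncol(p_n)), pixel_size_um))
  mask <- binarize_sensitivity(resp, params)
  split_nuclei(mask, pixel_size_um, params)
}

#' Per-seed summary table
#'
#' @param seeds a [label_map] of nucleus seeds.
#' @return A tibble with label, centroid (row/col, 1-based), area in pixels
#'   and in square micrometers.
#' @export
seed_table <- function(seeds) {
  m <- seeds$labels
  labs <- setdiff(sort(unique(as.vector(m))), 0L)
  if (length(labs) == 0)
    return(tibble::tibble(label = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), area_px = integer(),
                          area_um2 = numeric()))
  idx <- which(m > 0)
  rr <- (idx - 1) %% nrow(m) + 1
  cc <- (idx - 1) %/% nrow(m) + 1
  f <- factor(m[idx], levels = labs)
  tibble::tibble(
    label = labs,
    centroid_row = as.numeric(tapply(rr, f, mean)),
    centroid_col = as.numeric(tapply(cc, f, mean)),
    area_px = as.integer(table(f)),
    area_um2 = as.integer(table(f)) * seeds$pixel_size_um^2)
}
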