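#' Parameters of the cell-delineation step
#'
#' @param gaussian_sigma_um denoising Gaussian scale applied to the
#'   intensity image before enhancement, in micrometers (default 1.3).
#' @param expected_cell_area_um2 expected mean area of one cell in square
#'   micrometers (default 600); an assay parameter set by the user, used
#'   with the detected nucleus count to pick the background threshold.
#' @param otsu_levels number of Otsu thresholds for background estimation
#'   (default 3).
#' @return A list of class `cell_params`.
#' @export
cell_params <- function(gaussian_sigma_um = 1.3,
                        expected_cell_area_um2 = 600, otsu_levels = 3) {
  if (gaussian_sigma_um <= 0 || expected_cell_area_um2 <= 0 ||
      otsu_levels < 1)
    stop("all cell parameters must be positive")
  structure(list(gaussian_sigma_um = gaussian_sigma_um,
                 expected_cell_area_um2 = expected_cell_area_um2,
                 otsu_levels = as.integer(otsu_levels)),
            class = "cell_params")
}

#' Probability-enhanced cell intensity map
#'
#' Builds the watershed topography for cell delineation: the intensity image
#' is Gaussian-denoised, robustly scaled to \[0, 255\] (0.1/99.9
#' percentiles), log-transformed (`log1p`), and multiplied pixelwise by the
#' cytoplasm probability map. Bright cytoplasm with high cytoplasm
#' probability gives large values; background and nuclei stay low.
#'
#' @param img an [image2d] (preprocessed intensity image).
#' @param p_c cytoplasm probability map, same shape.
#' @param params a [cell_params].
#' @return Nonnegative matrix of enhanced values.
#' @export
enhance_cells <- function(img, p_c, params = cell_params()) {
  stopifnot(is_image2d(img))
  if (!identical(dim(img$pixels), dim(p_c)))
    stop("image and probability map shapes differ")
  sig_px <- params$gaussian_sigma_um / img$pixel_size_um
  g <- as.matrix(EBImage::gblur(img$pixels, sigma = sig_px,
                                boundary = "replicate"))
  scaled <- normalize_intensity(g) * 255
  log1p(scaled) * p_c
}

#' Estimate the background mask by expected-area Otsu selection
#'
#' Computes `otsu_levels` (default three) multi-level Otsu thresholds of the
#' enhanced map, then scans a fine grid of candidate thresholds spanning the
#' interval from the lowest to the highest Otsu threshold and picks the
#' candidate whose foreground area is closest to the expected total cell
#' area `n_seeds * expected_cell_area_um2` (converted to pixels). Background
#' is everything below the chosen threshold.
#'
#' @param enhanced matrix from [enhance_cells()].
#' @param n_seeds number of detected nuclei (>= 1).
#' @param pixel_size_um micrometers per pixel.
#' @param params a [cell_params].
#' @param n_candidates size of the candidate grid (default 64).
#' @return Logical background mask; attributes `threshold`,
#'   `expected_area_px` and `foreground_area_px`.
#' @export
estimate_background <- function(enhanced, n_seeds, pixel_size_um,
                                params = cell_params(), n_candidates = 64) {
  if (n_seeds < 1) stop("no seeds; nothing to segment")
  a_star <- n_seeds * params$expected_cell_area_um2 / pixel_size_um^2
  th <- multilevel_otsu(enhanced, params$otsu_levels)
  grid <- seq(th[1], th[length(th)], length.out = n_candidates)
  areas <- vapply(grid, function(t) sum(enhanced >= t), numeric(1))
  best <- which.min(abs(areas - a_star))
  mask <- enhanced < grid[best]
  attr(mask, "threshold") <- grid[best]
  attr(mask, "expected_area_px") <- a_star
  attr(mask, "foreground_area_px") <- areas[best]
  mask
}

#' Remove cell-interior components from a background marker
#'
#' The thresholded background mask also covers the dark nucleus
#' neighborhoods and dark texture pockets inside cells (the nucleus carries
#' little signal, and the probability-enhanced map is near zero there).
#' Used directly as a watershed marker those pockets would punch holes into
#' the cells, so components of the background mask that touch a seed and
#' are smaller than one expected cell area are dropped from the marker;
#' the seed flood then claims them. The true outer background is far larger
#' than a cell and is never dropped.
#'
#' @param background logical background mask.
#' @param seeds a [label_map] of nucleus seeds.
#' @param max_area_px size cutoff in pixels (one expected cell area).
#' @return Logical mask: the cleaned background marker.
#' @export
refine_background_marker <- function(background, seeds, max_area_px) {
  sm <- label_matrix(seeds)
  bg <- background & !(sm > 0)
  comps <- cpp_label8(matrix(as.integer(bg), nrow(bg), ncol(bg)))
  ncomp <- max(comps)
  if (ncomp == 0) return(bg)
  near_seed <- as.matrix(EBImage::dilate(matrix(as.numeric(sm > 0),
                                                nrow(sm), ncol(sm)),
                                         EBImage::makeBrush(3, "box"))) > 0
  touching <- unique(comps[near_seed & comps > 0])
  sizes <- tabulate(comps[comps > 0], ncomp)
  drop <- intersect(touching, which(sizes < max_area_px))
  if (length(drop)) bg[comps %in% drop] <- FALSE
  bg
}

#' Seeded-watershed delineation of whole cells
#'
#' Floods the negated enhanced map (so flooding proceeds from bright
#' cytoplasm toward dim boundaries) from the nucleus seed labels plus one
#' extra marker covering the estimated background. Each seed grows into
#' exactly one 8-connected cell containing it; the region claimed by the
#' background marker becomes 0. Seed pixels overlapping the background mask
#' are carved out of the background marker first (with a message).
#'
#' @param enhanced matrix from [enhance_cells()].
#' @param seeds a [label_map] of nucleus seeds (nonempty).
#' @param background logical background mask from [estimate_background()].
#' @return A [label_map] of cells; its positive label set equals the seed
#'   label set.
#' @export
segment_cells <- function(enhanced, seeds, background) {
  sm <- label_matrix(seeds)
  if (!any(sm > 0)) stop("empty seeds; nothing to segment")
  if (!identical(dim(sm), dim(enhanced)))
    stop("seed map and enhanced map shapes differ")
  overlap <- background & sm > 0
  if (any(overlap)) {
    message(sum(overlap), " seed pixel(s) overlapped the background mask; ",
            "carved out of the background marker")
    background <- background & !(sm > 0)
  }
  bg_label <- max(sm) + 1L
  markers <- sm
  markers[background] <- bg_label
  ones <- matrix(1L, nrow(sm), ncol(sm))
  lab <- cpp_watershed(-enhanced, markers, ones)
  lab[lab == bg_label] <- 0L
  label_map(lab, if (is_label_map(seeds)) seeds$pixel_size_um else 1)
}

#' Segment one image end to end
#'
#' Composition of the full pipeline: preprocessing (top-hat illumination
#' correction, resampling to the reference pixel size), network inference,
#' nucleus-seed detection and seeded-watershed cell delineation. All
#' intermediates are returned.
#'
#' @param img an [image2d] (raw; preprocessing is applied here using the
#'   parameters embedded in the model).
#' @param model a `unet_model`.
#' @param seed_opts a [seed_params].
#' @param cell_opts a [cell_params].
#' @param preprocess apply top-hat and resampling first (default TRUE; set
#'   to FALSE when `img` is already preprocessed).
#' @return A list of class `segmentation` with elements `cells`, `nuclei`
#'   (both [label_map]s, the nucleus labels a subset of the cell labels with
#'   equal ids), `probmaps`, `image` (the preprocessed image) and
#'   `enhanced`. With zero detected seeds the maps are empty and a warning
#'   is raised.
#' @export
segment_image <- function(img, model, seed_opts = seed_params(),
                          cell_opts = cell_params(), preprocess = TRUE) {
  stopifnot(inherits(model, "unet_model"))
  if (preprocess) {
    img <- tophat_correct(img, model$preprocess$tophat_kernel_px)
    img <- resample_to_reference(img, model$preprocess$target_pixel_size_um)
  }
  pm <- infer_probmaps(img, model)
  nuclei <- detect_seeds(pm$p_n, img$pixel_size_um, seed_opts)
  if (n_objects(nuclei) == 0) {
    warning("no nucleus seeds detected; returning an empty segmentation")
    empty <- label_map(matrix(0L, nrow(img$pixels), ncol(img$pixels)),
                       img$pixel_size_um)
    return(structure(list(cells = empty, nuclei = empty, probmaps = pm,
                          image = img, enhanced = NULL),
                     class = "segmentation"))
  }
  enh <- enhance_cells(img, pm$p_c, cell_opts)
  bg <- estimate_background(enh, n_objects(nuclei), img$pixel_size_um,
                            cell_opts)
  bg <- refine_background_marker(bg, nuclei,
                                 cell_opts$expected_cell_area_um2 /
                                   img$pixel_size_um^2)
  cells <- segment_cells(enh, nuclei, bg)
  structure(list(cells = cells, nuclei = nuclei, probmaps = pm, image = img,
                 enhanced = enh),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d cell(s) on a %d x %d image\n",
              n_objects(x$cells), nrow(x$image$pixels),
              ncol(x$image$pixels)))
  invisible(x)
}

#' Per-cell feature table
#'
#' @param seg a `segmentation` (or a list with `cells`, `nuclei`, `image`).
#' @return A tibble with one row per cell: label, areas (pixels and um^2),
#'   centroid, mean intensity and nucleus area.
#' @export
cell_table <- function(seg) {
  cm <- seg$cells$labels; nm <- seg$nuclei$labels
  px <- seg$image$pixels
  ps <- seg$cells$pixel_size_um
  labs <- setdiff(sort(unique(as.vector(cm))), 0L)
  if (length(labs) == 0)
    return(tibble::tibble(label = integer(), area_px = integer(),
                          area_um2 = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(),
                          mean_intensity = numeric(),
                          nucleus_area_px = integer()))
  idx <- which(cm > 0)
  f <- factor(cm[idx], levels = labs)
  rr <- (idx - 1) %% nrow(cm) + 1
  cc <- (idx - 1) %/% nrow(cm) + 1
  narea <- tabulate(factor(nm[nm > 0], levels = labs), length(labs))
  tibble::tibble(
    label = labs,
    area_px = as.integer(table(f)),
    area_um2 = as.integer(table(f)) * ps^2,
    centroid_row = as.numeric(tapply(rr, f, mean)),
    centroid_col = as.numeric(tapply(cc, f, mean)),
    mean_intensity = as.numeric(tapply(px[idx], f, mean)),
    nucleus_area_px = narea)
}

#' Color contour overlay of a segmentation
#'
#' @param seg a `segmentation`.
#' @return An H x W x 3 RGB array in \[0, 1\]: the intensity image in gray
#'   with cell boundaries in color (one of six hues per label).
#' @export
overlay_rgb <- function(seg) {
  px <- normalize_intensity(seg$image$pixels)
  cm <- seg$cells$labels
  edge <- boundary_pixels(cm)
  cols <- grDevices::col2rgb(c("red", "yellow", "green", "cyan", "magenta",
                               "orange")) / 255
  out <- array(rep(px, 3), c(dim(px), 3))
  idx <- which(edge)
  hue <- (cm[idx] - 1) %% ncol(cols) + 1
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[idx] <- cols[ch, hue]
    out[, , ch] <- pl
  }
  out
}

# pixels whose 4-neighborhood contains a different label
boundary_pixels <- function(m) {
  H <- nrow(m); W <- ncol(m)
  e <- matrix(FALSE, H, W)
  e[-H, ] <- e[-H, ] | (m[-H, ] != m[-1, ])
  e[-1, ] <- e[-1, ] | (m[-1, ] != m[-H, ])
  e[, -W] <- e[, -W] | (m[, -W] != m[, -1])
  e[, -1] <- e[, -1] | (m[, -1] != m[, -W])
  e & m > 0
}
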