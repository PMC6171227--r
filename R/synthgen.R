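#' Configuration of the synthetic microscopy generator
#'
#' Renders the image class the segmentation pipeline is built for: bright
#' textured cytoplasm on a dark background, with nuclei whose intensity sits
#' near the background level, optional smooth uneven illumination, additive
#' noise, and a controllable fraction of touching cells. Exact cell and
#' nucleus label maps are returned alongside the image.
#'
#' Defaults describe a desk-scale field of view: a 512x512 frame at the
#' 0.65 um reference pixel size, 25 cells with radii 12-16 um (areas around
#' the 600 um^2 the cell-delineation step assumes), nuclei of 4-7 um radius
#' (inside the 2-8 um blob-detection scale range), cytoplasm mean intensity
#' 80 with 35% multiplicative band-limited texture, nuclei at 22 on a
#' background of 20 (a camera-offset-scale baseline with the nuclear signal
#' sitting within one noise sd of it — the near-background nuclei that
#' motivate a learned nucleus detector), Gaussian noise with sd 2, and a
#' 15% smooth illumination gradient.
#'
#' @param image_size_px frame side in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param n_cells number of cells to place (0 allowed).
#' @param cell_radius_um range (min, max) of cell equivalent radii, um.
#' @param nucleus_radius_um range of nucleus radii, um; the maximum must be
#'   smaller than the cell minimum so nuclei fit strictly inside cells.
#' @param cyto_intensity mean cytoplasm intensity.
#' @param texture_amplitude relative amplitude of the multiplicative
#'   band-limited cytoplasm texture.
#' @param nucleus_intensity nucleus intensity (must be below
#'   `cyto_intensity`; near `background_intensity` by design).
#' @param background_intensity background level.
#' @param psf_sigma_um optical blur: the noiseless scene is convolved with
#'   a Gaussian point-spread function of this width (um) before noise is
#'   added, giving the soft intensity ramps of real micrographs (0
#'   disables).
#' @param noise_sd additive Gaussian noise sd.
#' @param illumination_amplitude relative amplitude of the smooth
#'   multiplicative illumination field (0 disables it).
#' @param touching_fraction fraction of cells placed in contact with an
#'   already placed cell (centers at sub-diameter distance).
#' @param seed optional RNG seed for reproducible rendering.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_size_px = 512, pixel_size_um = 0.65,
                         n_cells = 25, cell_radius_um = c(12, 16),
                         nucleus_radius_um = c(4, 7), cyto_intensity = 80,
                         texture_amplitude = 0.35, nucleus_intensity = 22,
                         background_intensity = 20, psf_sigma_um = 0.8,
                         noise_sd = 2,
                         illumination_amplitude = 0.15,
                         touching_fraction = 0.25, seed = NULL) {
  if (max(nucleus_radius_um) >= min(cell_radius_um))
    stop("nucleus radii must be strictly smaller than cell radii")
  if (nucleus_intensity >= cyto_intensity)
    stop("`nucleus_intensity` must be below `cyto_intensity` (the contrast ",
         "the whole method assumes)")
  if (any(c(cyto_intensity, nucleus_intensity, background_intensity) < 0))
    stop("intensities must be nonnegative")
  if (touching_fraction < 0 || touching_fraction > 1)
    stop("`touching_fraction` must lie in [0, 1]")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 cell_radius_um = cell_radius_um,
                 nucleus_radius_um = nucleus_radius_um,
                 cyto_intensity = cyto_intensity,
                 texture_amplitude = texture_amplitude,
                 nucleus_intensity = nucleus_intensity,
                 background_intensity = background_intensity,
                 psf_sigma_um = psf_sigma_um, noise_sd = noise_sd,
                 illumination_amplitude = illumination_amplitude,
                 touching_fraction = touching_fraction, seed = seed),
            class = "synth_config")
}

with_preserved_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# band-limited unit-scale random field: white noise blurred at `sigma`,
# scaled to zero mean and max |.| = 1
smooth_field <- function(n, sigma) {
  f <- matrix(rnorm(n * n), n, n)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma, boundary = "replicate"))
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

# very-low-frequency field (illumination): a coarse random grid
# interpolated up to the frame, zero mean, max |.| = 1. A 3x3 grid keeps
# the variation at the frame scale, as for real vignetting / uneven
# excitation (and hence wider than the top-hat kernel, which only removes
# structure wider than itself).
gradient_field <- function(n) {
  f <- matrix(rnorm(9), 3, 3)
  f <- as.matrix(EBImage::resize(f, w = n, h = n))
  f <- f - mean(f)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate one synthetic image with exact ground truth
#'
#' Cells are ellipses with randomized axis ratio and orientation; overlap
#' between touching cells is resolved by nearest-scaled-center assignment so
#' the cell labels remain a partition. Each cell contains exactly one
#' elliptical nucleus (same label id) strictly inside it. Rendering order:
#' cytoplasm texture and nucleus/background levels, multiplicative
#' illumination field, additive Gaussian noise, clamp at zero.
#'
#' @param cfg a [synth_config].
#' @return A list with `image` ([image2d]), `cells` and `nuclei`
#'   ([label_map]s). Identical configurations (including seed) render
#'   identical triples.
#' @export
generate_image <- function(cfg = synth_config()) {
  with_preserved_rng(cfg$seed, {
    n <- cfg$image_size_px
    ps <- cfg$pixel_size_um
    cells <- matrix(0L, n, n)
    nuclei <- matrix(0L, n, n)
    if (cfg$n_cells > 0) {
      geom <- place_cells(cfg)
      qbest <- matrix(Inf, n, n)
      for (i in seq_len(nrow(geom))) {
        q <- ellipse_dist(n, geom$row[i], geom$col[i], geom$a[i], geom$b[i],
                          geom$theta[i])
        inside <- q <= 1 & q < qbest
        cells[inside] <- i
        qbest[inside] <- q[inside]
      }
      for (i in seq_len(nrow(geom))) {
        rn <- runif(1, cfg$nucleus_radius_um[1], cfg$nucleus_radius_um[2]) / ps
        jit <- 0.3 * (min(geom$a[i], geom$b[i]) - rn)
        ang <- runif(1, 0, 2 * pi)
        off <- runif(1, 0, max(jit, 0))
        qn <- ellipse_dist(n, geom$row[i] + off * cos(ang),
                           geom$col[i] + off * sin(ang),
                           rn * runif(1, 0.9, 1.1), rn, runif(1, 0, pi))
        nuclei[qn <= 1 & cells == i] <- i
      }
    }
    img <- matrix(cfg$background_intensity, n, n)
    cyto <- cells > 0 & nuclei == 0
    tex <- smooth_field(n, sigma = 4)
    tex <- tex / max(stats::sd(tex), 1e-12)
    img[cyto] <- cfg$cyto_intensity *
      pmax(1 + cfg$texture_amplitude * tex[cyto], 0.3)
    img[nuclei > 0] <- cfg$nucleus_intensity
    if (cfg$psf_sigma_um > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = cfg$psf_sigma_um / ps,
                                      boundary = "replicate"))
    if (cfg$illumination_amplitude > 0) {
      illum <- 1 + cfg$illumination_amplitude * gradient_field(n)
      img <- img * illum
    }
    img <- img + rnorm(n * n, 0, cfg$noise_sd)
    img[img < 0] <- 0
    list(image = image2d(img, ps),
         cells = label_map(cells, ps),
         nuclei = label_map(nuclei, ps))
  })
}

# scaled squared ellipse coordinate: <= 1 inside
ellipse_dist <- function(n, r0, c0, a, b, theta) {
  rr <- matrix(seq_len(n), n, n) - r0
  cc <- matrix(seq_len(n), n, n, byrow = TRUE) - c0
  u <- (rr * cos(theta) + cc * sin(theta)) / a
  v <- (-rr * sin(theta) + cc * cos(theta)) / b
  u^2 + v^2
}

place_cells <- function(cfg) {
  n <- cfg$image_size_px; ps <- cfg$pixel_size_um
  rows <- cols <- a <- b <- theta <- rad <- numeric(0)
  for (i in seq_len(cfg$n_cells)) {
    r_um <- runif(1, cfg$cell_radius_um[1], cfg$cell_radius_um[2])
    r_px <- r_um / ps
    e <- runif(1, 0.85, 1.2)
    ai <- r_px * e; bi <- r_px / e
    rmax <- max(ai, bi)
    touching <- length(rows) > 0 && runif(1) < cfg$touching_fraction
    placed <- FALSE
    for (try in seq_len(500)) {
      if (touching) {
        j <- sample.int(length(rows), 1)
        d <- (rad[j] + r_px) * runif(1, 0.75, 0.95)
        ang <- runif(1, 0, 2 * pi)
        ri <- rows[j] + d * cos(ang); ci <- cols[j] + d * sin(ang)
        if (ri < rmax + 2 || ri > n - rmax - 1 || ci < rmax + 2 ||
            ci > n - rmax - 1) next
        ok <- all(sqrt((rows - ri)^2 + (cols - ci)^2) >
                    0.70 * (rad + r_px))
      } else {
        ri <- runif(1, rmax + 2, n - rmax - 1)
        ci <- runif(1, rmax + 2, n - rmax - 1)
        ok <- length(rows) == 0 ||
          all(sqrt((rows - ri)^2 + (cols - ci)^2) > 1.05 * (rad + r_px))
      }
      if (ok) {
        rows <- c(rows, ri); cols <- c(cols, ci)
        a <- c(a, ai); b <- c(b, bi); theta <- c(theta, runif(1, 0, pi))
        rad <- c(rad, r_px)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place cell ", i, " after 500 attempts; use fewer or ",
           "smaller cells (or a larger frame)")
  }
  data.frame(row = rows, col = cols, a = a, b = b, theta = theta)
}

#' Generate a reproducible synthetic dataset
#'
#' Per-image seeds are derived deterministically from the master seed, and
#' the training label triplet of every image is built from the exact ground
#' truth with [labels_from_segmentation()].
#'
#' @param n_images number of images (>= 1).
#' @param cfg a [synth_config] (its own `seed` field is ignored here).
#' @param seed master seed.
#' @return A list of `n_images` elements, each with `image`, `labels`
#'   (a [label_triplet]), `cells` and `nuclei`.
#' @export
generate_dataset <- function(n_images, cfg = synth_config(), seed = 1) {
  if (n_images < 1) stop("`n_images` must be at least 1")
  lapply(seq_len(n_images), function(i) {
    cfg$seed <- (as.integer(seed) %% 100003L) * 20011L + i * 7919L
    g <- generate_image(cfg)
    list(image = g$image,
         labels = labels_from_segmentation(g$cells, g$nuclei),
         cells = g$cells, nuclei = g$nuclei)
  })
}
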