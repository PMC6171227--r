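#' Reconciled layer table of the pixel-classifier network
#'
#' The network is an asymmetric UNet: a five-stage contracting path with
#' 3x3 convolutions of 32, 64, 128, 128 and 256 filters (each followed by a
#' 2x2 stride-2 max pool), and an expanding path of 2x2 stride-2 transposed
#' convolutions and 3x3 convolutions with skip concatenations at the 1/2,
#' 1/4 and 1/8 resolutions (concatenated widths 160, 192 and 256) and three
#' dropout layers at rate 0.5 (bottleneck and the two deepest
#' concatenations). A 1x1 convolution with a per-channel sigmoid produces the
#' three probability maps; sigmoid (rather than softmax) is used because the
#' training loss penalizes the three channels independently and carries an
#' explicit sum-to-one term, so normalization is not built into the network.
#' Spatial sizes are listed for the canonical 160x160 core; the implementation
#' runs on the full 176x176 tile (ceil-mode pooling with crop-to-skip), so the
#' 8-pixel halo around the core contributes context.
#'
#' @return A tibble describing the layer sequence.
#' @export
unet_spec <- function() {
  tibble::tibble(
    stage = c(rep("encoder", 11), "bottleneck",
              rep("decoder", 19), "output"),
    layer = c(
      "input 1ch", "conv 3x3, 32", "maxpool 2x2",
      "conv 3x3, 64", "maxpool 2x2", "conv 3x3, 128", "maxpool 2x2",
      "conv 3x3, 128", "maxpool 2x2", "conv 3x3, 256", "maxpool 2x2",
      "dropout 0.5",
      "deconv 2x2, 256", "conv 3x3, 128", "deconv 2x2, 128",
      "conv 3x3, 128", "concat (+128 skip)", "dropout 0.5",
      "conv 3x3, 128", "deconv 2x2, 128", "conv 3x3, 128",
      "concat (+64 skip)", "dropout 0.5", "conv 3x3, 128",
      "deconv 2x2, 128", "conv 3x3, 128", "concat (+32 skip)",
      "conv 3x3, 64", "deconv 2x2, 64", "conv 3x3, 64", "conv 1x1, 3",
      "sigmoid"),
    channels_out = c(1, 32, 32, 64, 64, 128, 128, 128, 128, 256, 256, 256,
                     256, 128, 128, 128, 256, 256, 128, 128, 128, 192, 192,
                     128, 128, 128, 160, 64, 64, 64, 3, 3),
    core_size = c(160, 160, 80, 80, 40, 40, 20, 20, 10, 10, 5, 5,
                  10, 10, 20, 20, 20, 20, 20, 40, 40, 40, 40, 40,
                  80, 80, 80, 80, 160, 160, 160, 160))
}

#' Weights of the training loss
#'
#' The loss is a weighted sum of per-channel root-mean-square deviations
#' between predictions and labels (nuclei, cytoplasm, background) plus a
#' term `w * RMSD(l_n + l_c + l_b, 1)` that reports how far the labels are
#' from a per-pixel partition. All four weights default to 1.
#'
#' @param w_n,w_c,w_b,w nonnegative weights; at least one must be positive.
#' @return A named numeric vector of class `loss_weights`.
#' @export
loss_weights <- function(w_n = 1, w_c = 1, w_b = 1, w = 1) {
  v <- c(w_n = w_n, w_c = w_c, w_b = w_b, w = w)
  if (any(v < 0)) stop("loss weights must be nonnegative")
  if (all(v == 0)) stop("at least one loss weight must be positive")
  structure(v, class = "loss_weights")
}

#' Training-loss value for a prediction / label pair
#'
#' `unet_loss(pred, labels, weights)` evaluates
#' `w_n RMSD(p_n, l_n) + w_c RMSD(p_c, l_c) + w_b RMSD(p_b, l_b) +
#'  w RMSD(l_n + l_c + l_b, 1)` with `RMSD(a, b) = sqrt(mean((a - b)^2))`
#' over all pixels. The fourth term depends on the labels only: degraded
#' labels that fail to partition the image are penalized rather than
#' rejected.
#'
#' @param pred a [probmaps] object (or list with `p_n`, `p_c`, `p_b`).
#' @param labels a [label_triplet] (or list with `l_n`, `l_c`, `l_b`).
#' @param weights a [loss_weights] vector.
#' @return Nonnegative scalar loss.
#' @export
unet_loss <- function(pred, labels, weights = loss_weights()) {
  if (!identical(dim(pred$p_n), dim(labels$l_n)))
    stop("prediction and label shapes differ")
  rmsd <- function(a, b) sqrt(mean((a - b)^2))
  unname(weights[1] * rmsd(pred$p_n, labels$l_n) +
         weights[2] * rmsd(pred$p_c, labels$l_c) +
         weights[3] * rmsd(pred$p_b, labels$l_b) +
         weights[4] * rmsd(labels$l_n + labels$l_c + labels$l_b, 1))
}

#' Binary training masks for the three classes
#'
#' @param l_n,l_c,l_b binary (0/1) matrices of one shape: nuclei, cytoplasm
#'   and background masks. A perfect label set partitions the image
#'   (`l_n + l_c + l_b == 1` everywhere); deviations are allowed and are
#'   penalized through the loss, not rejected here.
#' @return An object of class `label_triplet`.
#' @export
label_triplet <- function(l_n, l_c, l_b) {
  for (m in list(l_n, l_c, l_b)) {
    if (!is.matrix(m) || !identical(dim(m), dim(l_n)))
      stop("label masks must be matrices of one shape")
    if (!all(m %in% c(0, 1))) stop("label masks must be binary")
  }
  structure(list(l_n = l_n, l_c = l_c, l_b = l_b), class = "label_triplet")
}

#' Derive the training label triplet from a segmentation
#'
#' Converts a cell label map and a nucleus label map into the three binary
#' training masks: nuclei, cytoplasm (inside a cell but not a nucleus) and
#' background. The three masks partition the image by construction.
#'
#' @param cells,nuclei [label_map]s of one shape; every nucleus pixel must
#'   lie inside some cell.
#' @return A [label_triplet].
#' @export
labels_from_segmentation <- function(cells, nuclei) {
  cm <- label_matrix(cells); nm <- label_matrix(nuclei)
  if (!identical(dim(cm), dim(nm))) stop("cell and nucleus maps differ in shape")
  outside <- nm > 0 & cm == 0
  if (any(outside)) {
    bad <- sort(unique(nm[outside]))
    stop("nucleus label(s) ", paste(bad, collapse = ", "),
         " have pixels outside every cell")
  }
  l_n <- (nm > 0) * 1
  l_c <- (cm > 0 & nm == 0) * 1
  l_b <- (cm == 0) * 1
  label_triplet(l_n, l_c, l_b)
}

#' Tiling grid for patch-wise training and inference
#'
#' Splits an image into 160x160 cores that exactly partition it (the last
#' row/column of cores is truncated at the boundary) and associates each
#' core with a 176x176 tile centered on it: an 8-pixel halo on every side,
#' realized by mirror padding where the tile overhangs the image. Adjacent
#' tiles therefore overlap by 16 pixels while the cores are disjoint, so
#' stitching core predictions needs no blending.
#'
#' @param height,width image dimensions in pixels.
#' @param core core side (default 160).
#' @param halo halo width per side (default 8).
#' @return A tibble with one row per tile: core origin and size, and the
#'   (possibly negative / overhanging) tile origin; tile side is
#'   `core + 2 * halo`. Attributes `core`, `halo`, `height`, `width`.
#' @examples
#' g <- make_patch_grid(2048, 2048)
#' nrow(g)  # 13 x 13 cores
#' @export
make_patch_grid <- function(height, width, core = 160L, halo = 8L) {
  stopifnot(height >= 1, width >= 1)
  r0 <- seq(0L, height - 1L, by = core)
  c0 <- seq(0L, width - 1L, by = core)
  g <- expand.grid(core_row = r0, core_col = c0)
  g$core_h <- pmin(core, height - g$core_row)
  g$core_w <- pmin(core, width - g$core_col)
  g$tile_row <- g$core_row - halo
  g$tile_col <- g$core_col - halo
  out <- tibble::as_tibble(g)
  attr(out, "core") <- core
  attr(out, "halo") <- halo
  attr(out, "tile") <- core + 2L * halo
  attr(out, "height") <- height
  attr(out, "width") <- width
  out
}

# mirror (reflect-101) index lookup, 1-based, for windows overhanging an
# n-length axis; wraps for windows larger than the image
reflect_index <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n - 2L)
  ifelse(j >= n, 2L * n - 2L - j, j) + 1L
}

# extract an h x w window with top-left (r0, c0) (0-based), mirror-padded
extract_window <- function(m, r0, c0, h, w) {
  ri <- reflect_index(r0 + seq_len(h), nrow(m))
  ci <- reflect_index(c0 + seq_len(w), ncol(m))
  m[ri, ci, drop = FALSE]
}

rotate90 <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Construct the pixel-classifier network
#'
#' Builds the UNet of [unet_spec()] with freshly initialized weights
#' (He-scaled normal draws from R's RNG, so construction is reproducible
#' under `set.seed()`).
#'
#' @param spec layer table, by default [unet_spec()]; passing a table whose
#'   encoder widths differ from the supported architecture is an error
#'   naming the offending layer.
#' @return An object of class `unet_model`.
#' @export
build_network <- function(spec = unet_spec()) {
  ref <- unet_spec()
  if (!identical(spec$channels_out, ref$channels_out) ||
      !identical(spec$layer, ref$layer)) {
    bad <- which(spec$layer != ref$layer | spec$channels_out !=
                   ref$channels_out)[1]
    stop("unsupported layer specification at layer ", bad, " ('",
         spec$layer[bad], "'): the compiled network implements the fixed ",
         "32/64/128/128/256 architecture")
  }
  ptr <- unet_create()
  structure(list(ptr = ptr, spec = ref, n_params = unet_nparams(ptr),
                 trained = FALSE, loss_trace = NULL,
                 preprocess = list(target_pixel_size_um = 0.65,
                                   tophat_kernel_px = 200)),
            class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %s parameters, %s\n",
              format(x$n_params, big.mark = ","),
              if (x$trained) sprintf("trained (%d epochs)",
                                     length(x$loss_trace)) else "untrained"))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs number of passes over the patch set (default 30).
#' @param batch_size patches per weight update (default 32).
#' @param learning_rate Adam step size (default 0.001).
#' @param augment apply right-angle rotation augmentation: each sampled patch
#'   is used at a rotation drawn from 0/90/180/270 degrees (default TRUE).
#' @param dropout dropout rate of the three dropout layers (default 0.5).
#' @param patches_per_epoch optional cap on how many (randomly sampled)
#'   patches form one epoch; `NULL` uses every tile of every image.
#' @param seed optional RNG seed fixed at the start of training; two runs
#'   with the same seed on the same machine produce identical loss traces.
#' @param verbose log per-epoch mean loss (default TRUE).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 32, learning_rate = 0.001,
                         augment = TRUE, dropout = 0.5,
                         patches_per_epoch = NULL, seed = NULL,
                         verbose = TRUE) {
  if (epochs < 1) stop("`epochs` must be at least 1")
  if (batch_size < 1) stop("`batch_size` must be at least 1")
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, augment = isTRUE(augment),
                 dropout = dropout,
                 patches_per_epoch = patches_per_epoch, seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Train the pixel classifier
#'
#' Minimizes the weighted RMSD loss (see [unet_loss()]) over 176x176 tiles
#' whose central 160x160 cores partition each training image; the loss is
#' evaluated on the core only. Images must already be preprocessed
#' ([tophat_correct()] then [resample_to_reference()]). Intensities are
#' scaled per image to robust [0, 1] before entering the network.
#'
#' @param dataset nonempty list; each element is a list with `image` (an
#'   [image2d]) and `labels` (a [label_triplet] of the same shape).
#' @param config a [train_config].
#' @param weights a [loss_weights] vector.
#' @param model optionally continue training an existing `unet_model`;
#'   by default a fresh network is built.
#' @return The trained `unet_model`, with the per-epoch mean loss in
#'   `$loss_trace`.
#' @export
train_unet <- function(dataset, config = train_config(),
                       weights = loss_weights(), model = NULL) {
  if (length(dataset) == 0) stop("training dataset is empty")
  for (d in dataset) {
    if (!is_image2d(d$image)) stop("each dataset element needs an `image`")
    if (!identical(dim(d$image$pixels), dim(d$labels$l_n)))
      stop("image and label shapes differ")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(model)) model <- build_network()
  tile <- 176L; core <- 160L; halo <- 8L

  # precompute per-image normalized intensities and tile index
  imgs <- lapply(dataset, function(d) normalize_intensity(d$image$pixels))
  grids <- lapply(dataset, function(d)
    make_patch_grid(nrow(d$image$pixels), ncol(d$image$pixels)))
  index <- do.call(rbind, lapply(seq_along(grids), function(i)
    cbind(img = i, tile_row = grids[[i]]$tile_row,
          tile_col = grids[[i]]$tile_col)))

  loss_trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(index))
    if (!is.null(config$patches_per_epoch))
      ord <- ord[seq_len(min(config$patches_per_epoch, length(ord)))]
    losses <- c()
    for (start in seq(1, length(ord), by = config$batch_size)) {
      take <- ord[start:min(start + config$batch_size - 1, length(ord))]
      B <- length(take)
      x <- array(0, c(tile, tile, B))
      y <- array(0, c(tile, tile, 3, B))
      for (s in seq_len(B)) {
        i <- index[take[s], "img"]
        r0 <- index[take[s], "tile_row"]; c0 <- index[take[s], "tile_col"]
        k <- if (config$augment) sample.int(4, 1) - 1 else 0
        x[, , s] <- rotate90(extract_window(imgs[[i]], r0, c0, tile, tile), k)
        lt <- dataset[[i]]$labels
        y[, , 1, s] <- rotate90(extract_window(lt$l_n, r0, c0, tile, tile), k)
        y[, , 2, s] <- rotate90(extract_window(lt$l_c, r0, c0, tile, tile), k)
        y[, , 3, s] <- rotate90(extract_window(lt$l_b, r0, c0, tile, tile), k)
      }
      l <- unet_train_batch(model$ptr, x, y, config$learning_rate,
                            config$dropout, as.numeric(weights),
                            halo, core, core)
      losses <- c(losses, l)
    }
    loss_trace[ep] <- mean(losses)
    if (config$verbose)
      message(sprintf("epoch %d/%d: mean loss %.5f", ep, config$epochs,
                      loss_trace[ep]))
  }
  model$trained <- TRUE
  model$loss_trace <- c(model$loss_trace, loss_trace)
  model$train_config <- config
  model
}

# robust per-image scaling to [0, 1] (0.1 / 99.9 intensity percentiles)
normalize_intensity <- function(px) {
  q <- quantile(px, c(0.001, 0.999), names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(px), ncol(px)))
  out <- (px - q[1]) / (q[2] - q[1])
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Predict class probability maps for a whole image
#'
#' Runs the network over the tiling grid of [make_patch_grid()] and writes
#' each predicted 160x160 core into place; cores are disjoint so no blending
#' is involved. The image must be preprocessed the same way as the training
#' data.
#'
#' @param img an [image2d] (preprocessed).
#' @param model a `unet_model`.
#' @return A [probmaps] object of the full image.
#' @export
infer_probmaps <- function(img, model) {
  stopifnot(inherits(model, "unet_model"), is_image2d(img))
  px <- normalize_intensity(img$pixels)
  d <- dim(px)
  g <- make_patch_grid(d[1], d[2])
  halo <- attr(g, "halo"); tile <- attr(g, "tile")
  p_n <- matrix(0, d[1], d[2]); p_c <- p_n; p_b <- p_n
  for (i in seq_len(nrow(g))) {
    tl <- extract_window(px, g$tile_row[i], g$tile_col[i], tile, tile)
    pr <- unet_predict(model$ptr, tl)
    rr <- g$core_row[i] + seq_len(g$core_h[i])
    cc <- g$core_col[i] + seq_len(g$core_w[i])
    p_n[rr, cc] <- pr[halo + seq_len(g$core_h[i]),
                      halo + seq_len(g$core_w[i]), 1]
    p_c[rr, cc] <- pr[halo + seq_len(g$core_h[i]),
                      halo + seq_len(g$core_w[i]), 2]
    p_b[rr, cc] <- pr[halo + seq_len(g$core_h[i]),
                      halo + seq_len(g$core_w[i]), 3]
  }
  probmaps(p_n, p_c, p_b, img$pixel_size_um)
}

#' Save / load a trained model
#'
#' The file embeds the network weights, the layer table and the
#' preprocessing parameters (target pixel size, top-hat kernel), so
#' segmentation of a new image needs the model file only.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  state <- list(weights = unet_get_weights(model$ptr), spec = model$spec,
                trained = model$trained, loss_trace = model$loss_trace,
                preprocess = model$preprocess)
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  model <- build_network()
  unet_set_weights(model$ptr, state$weights)
  model$trained <- state$trained
  model$loss_trace <- state$loss_trace
  model$preprocess <- state$preprocess
  model
}
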