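#' Full pipeline configuration
#'
#' Aggregates every tunable of the pipeline with its default: the 0.65 um
#' reference pixel size and 200-px top-hat kernel of the preprocessing, the
#' seed-detection parameters (sensitivity 60, five Otsu levels, h = 3 um),
#' the cell-delineation parameters, the training schedule (30 epochs, batch
#' 32, learning rate 0.001), the loss weights (all 1) and the similarity
#' weighting k = 0.6. Serializes losslessly to a single YAML file.
#'
#' @param target_pixel_size_um reference pixel size, um.
#' @param tophat_kernel_px top-hat structuring-element side, px.
#' @param seeds a [seed_params].
#' @param cells a [cell_params].
#' @param train a [train_config].
#' @param weights a [loss_weights].
#' @param k SM weighting factor.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_pixel_size_um = 0.65,
                            tophat_kernel_px = 200,
                            seeds = seed_params(), cells = cell_params(),
                            train = train_config(),
                            weights = loss_weights(), k = 0.6) {
  structure(list(target_pixel_size_um = target_pixel_size_um,
                 tophat_kernel_px = as.integer(tophat_kernel_px),
                 seeds = seeds, cells = cells, train = train,
                 weights = weights, k = k),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- list(target_pixel_size_um = config$target_pixel_size_um,
               tophat_kernel_px = config$tophat_kernel_px,
               seeds = unclass(config$seeds),
               cells = unclass(config$cells),
               train = unclass(config$train),
               weights = as.list(unclass(config$weights)),
               k = config$k)
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- y$train
  pipeline_config(
    target_pixel_size_um = y$target_pixel_size_um,
    tophat_kernel_px = y$tophat_kernel_px,
    seeds = do.call(seed_params, y$seeds),
    cells = do.call(cell_params, y$cells),
    train = train_config(epochs = tr$epochs, batch_size = tr$batch_size,
                         learning_rate = tr$learning_rate,
                         augment = tr$augment, dropout = tr$dropout,
                         patches_per_epoch = tr$patches_per_epoch,
                         seed = tr$seed, verbose = tr$verbose),
    weights = do.call(loss_weights, y$weights),
    k = y$k)
}
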