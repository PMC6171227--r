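test_that("generated label maps are exact and internally consistent", {
  g <- generate_image(synth_config(n_cells = 10, seed = 71,
                                   image_size_px = 256))
  expect_equal(n_objects(g$cells), 10)
  expect_equal(n_objects(g$nuclei), 10)
  # nucleus i inside cell i
  nm <- g$nuclei$labels; cm <- g$cells$labels
  expect_true(all(cm[nm > 0] == nm[nm > 0]))
  # contrast contract: nuclei darker than cytoplasm on average
  expect_lt(mean(g$image$pixels[nm > 0]),
            mean(g$image$pixels[cm > 0 & nm == 0]))

  empty <- generate_image(synth_config(n_cells = 0, seed = 72,
                                       image_size_px = 128))
  expect_equal(n_objects(empty$cells), 0)
  expect_true(all(empty$image$pixels >= 0))
})

test_that("generation is seed-deterministic and leaves the RNG state alone", {
  cfg <- synth_config(n_cells = 6, seed = 73, image_size_px = 192)
  a <- generate_image(cfg)
  set.seed(999); before <- runif(3)
  set.seed(999)
  b <- generate_image(cfg)   # must not disturb the outer RNG stream
  after <- runif(3)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$cells$labels, b$cells$labels)
  expect_identical(before, after)
})

test_that("infeasible placement fails with advice", {
  expect_error(generate_image(synth_config(n_cells = 200,
                                           image_size_px = 128,
                                           seed = 74)),
               "fewer or\\s+smaller")
})

test_that("datasets have distinct images and partition label triplets", {
  ds <- generate_dataset(3, synth_config(n_cells = 5, image_size_px = 160),
                         seed = 75)
  expect_length(ds, 3)
  expect_false(identical(ds[[1]]$image$pixels, ds[[2]]$image$pixels))
  expect_false(identical(ds[[2]]$image$pixels, ds[[3]]$image$pixels))
  for (d in ds) {
    s <- d$labels$l_n + d$labels$l_c + d$labels$l_b
    expect_true(all(s == 1))
  }
  expect_error(generate_dataset(0), "at least 1")
})

test_that("illumination is recoverable by the top-hat correction", {
  cfg <- synth_config(n_cells = 6, seed = 76, illumination_amplitude = 0.25)
  g <- generate_image(cfg)
  corrected <- tophat_correct(g$image, 200)
  off_cell <- g$cells$labels == 0
  # the opening tracks the illumination-modulated lower envelope, so the
  # off-cell residual sits on the noise scale rather than at the (larger)
  # baseline-times-illumination level of the raw image
  expect_lt(mean(corrected$pixels[off_cell]), 5 * cfg$noise_sd)
  # look only at background far from any cell, so smoothed values reflect
  # the illumination field rather than bleed-over from bright cell bodies
  far <- as.matrix(EBImage::distmap(matrix(as.numeric(g$cells$labels == 0),
                                           512, 512))) > 25
  raw_spread <- diff(range(EBImage::gblur(g$image$pixels, 4)[far]))
  cor_spread <- diff(range(EBImage::gblur(corrected$pixels, 4)[far]))
  expect_lt(cor_spread, raw_spread / 2)
})

test_that("touching fraction produces adjacent cells", {
  g <- generate_image(synth_config(n_cells = 20, touching_fraction = 0.6,
                                   seed = 77))
  cm <- g$cells$labels
  # count label pairs that are 4-adjacent somewhere
  touch <- unique(rbind(
    cbind(as.vector(cm[-1, ]), as.vector(cm[-nrow(cm), ])),
    cbind(as.vector(cm[, -1]), as.vector(cm[, -ncol(cm)]))))
  touch <- touch[touch[, 1] > 0 & touch[, 2] > 0 &
                   touch[, 1] != touch[, 2], , drop = FALSE]
  expect_gt(nrow(touch), 0)
})
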