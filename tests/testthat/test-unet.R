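test_that("loss reproduces hand-computed values and weight identities", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  labs <- label_triplet(ones, zeros, zeros)
  pred_perfect <- list(p_n = ones, p_c = zeros, p_b = zeros)
  expect_equal(unet_loss(pred_perfect, labs), 0)

  pred_half <- list(p_n = matrix(0.5, 2, 2), p_c = zeros, p_b = zeros)
  expect_equal(unet_loss(pred_half, labs), 0.5)  # RMSD(0.5, 1) alone

  expect_error(loss_weights(0, 0, 0, 0), "at least one")
  w0 <- loss_weights(); w0[] <- 0; class(w0) <- "loss_weights"
  expect_equal(unet_loss(pred_half, labs, w0), 0)

  bad <- list(p_n = matrix(0.5, 3, 3), p_c = matrix(0, 3, 3),
              p_b = matrix(0, 3, 3))
  expect_error(unet_loss(bad, labs), "differ")

  # degraded labels are penalized through the sum term, not rejected
  degr <- label_triplet(ones, ones, zeros)  # sums to 2 in every pixel
  pred_match <- list(p_n = ones, p_c = ones, p_b = zeros)
  expect_equal(unet_loss(pred_match, degr), 1)  # RMSD(2, 1)
})

test_that("loss is invariant under spatial permutation", {
  set.seed(81)
  p <- matrix(runif(36), 6, 6); l <- matrix(rbinom(36, 1, 0.5), 6, 6)
  perm <- sample(36)
  pred <- list(p_n = p, p_c = 1 - p, p_b = p * 0)
  labs <- label_triplet(l, 1 - l, l * 0)
  pred2 <- lapply(pred, function(m) matrix(m[perm], 6, 6))
  labs2 <- label_triplet(matrix(l[perm], 6, 6), matrix((1 - l)[perm], 6, 6),
                         matrix(0, 6, 6))
  expect_equal(unet_loss(pred, labs), unet_loss(pred2, labs2))
})

test_that("patch grids partition the image with 176-px tiles", {
  g <- make_patch_grid(2048, 2048)
  expect_equal(nrow(g), 13 * 13)
  expect_equal(sort(unique(g$core_row)), seq(0, 1920, by = 160))

  g1 <- make_patch_grid(160, 160)
  expect_equal(nrow(g1), 1)
  expect_equal(attr(g1, "tile"), 176)

  set.seed(82)
  for (rep in 1:25) {
    h <- sample(1:700, 1); w <- sample(1:700, 1)
    g <- make_patch_grid(h, w)
    cover <- matrix(0L, h, w)
    for (i in seq_len(nrow(g))) {
      rr <- g$core_row[i] + seq_len(g$core_h[i])
      cc <- g$core_col[i] + seq_len(g$core_w[i])
      cover[rr, cc] <- cover[rr, cc] + 1L
    }
    expect_true(all(cover == 1L))  # no gaps, no double coverage
  }
})

test_that("network construction is deterministic in size and seeded weights", {
  set.seed(83)
  m1 <- build_network()
  set.seed(83)
  m2 <- build_network()
  expect_gt(m1$n_params, 0)
  expect_equal(m1$n_params, m2$n_params)
  w1 <- wholecellseg:::unet_get_weights(m1$ptr)
  w2 <- wholecellseg:::unet_get_weights(m2$ptr)
  expect_identical(w1, w2)

  p <- wholecellseg:::unet_predict(m1$ptr, matrix(0, 176, 176))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))

  bad <- unet_spec()
  bad$channels_out[2] <- 48
  expect_error(build_network(bad), "layer 2")
})

test_that("inference is constant on constant images and stitches without seams", {
  set.seed(84)
  m <- build_network()
  img <- image2d(matrix(3.7, 200, 260), 0.65)
  pm <- infer_probmaps(img, m)
  for (ch in list(pm$p_n, pm$p_c, pm$p_b)) {
    expect_lt(diff(range(ch)), 1e-5)
    expect_true(all(ch >= 0 & ch <= 1))
  }
})

test_that("tiled inference equals direct single-tile prediction on small images", {
  set.seed(85)
  m <- build_network()
  for (d in list(c(160, 160), c(90, 150))) {
    px <- matrix(runif(prod(d)), d[1], d[2])
    pm <- infer_probmaps(image2d(px, 0.65), m)
    tile <- wholecellseg:::extract_window(wholecellseg:::normalize_intensity(px),
                                          -8L, -8L, 176L, 176L)
    direct <- wholecellseg:::unet_predict(m$ptr, tile)
    core <- direct[8 + seq_len(d[1]), 8 + seq_len(d[2]), ]
    expect_lt(max(abs(pm$p_n - core[, , 1])), 1e-5)
    expect_lt(max(abs(pm$p_c - core[, , 2])), 1e-5)
    expect_lt(max(abs(pm$p_b - core[, , 3])), 1e-5)
  }
})

test_that("training decreases the loss and is seed-reproducible", {
  ds <- generate_dataset(4, synth_config(image_size_px = 160, n_cells = 3),
                         seed = 86)
  ds <- lapply(ds, function(d)
    list(image = tophat_correct(d$image, 120), labels = d$labels))
  cfg <- train_config(epochs = 3, batch_size = 2, patches_per_epoch = 4,
                      seed = 87, verbose = FALSE)
  m1 <- train_unet(ds, cfg)
  expect_length(m1$loss_trace, 3)
  expect_lt(m1$loss_trace[3], m1$loss_trace[1])
  m2 <- train_unet(ds, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)

  expect_error(train_unet(list(), cfg), "empty")
  expect_error(train_config(epochs = 0), "at least 1")
  badds <- ds
  badds[[1]]$labels$l_n <- matrix(0, 10, 10)
  expect_error(train_unet(badds, cfg), "differ")
})

test_that("label triplets derived from segmentations partition the image", {
  empty <- label_map(matrix(0L, 20, 20), 0.65)
  lt <- labels_from_segmentation(empty, empty)
  expect_true(all(lt$l_b == 1))
  expect_true(all(lt$l_n == 0) && all(lt$l_c == 0))

  cells <- matrix(0L, 30, 30); cells[disk_mask(30, 30, 15, 15, 10)] <- 1L
  nuc <- matrix(0L, 30, 30); nuc[disk_mask(30, 30, 15, 15, 4)] <- 1L
  lt <- labels_from_segmentation(label_map(cells, 1), label_map(nuc, 1))
  expect_true(all(lt$l_n + lt$l_c + lt$l_b == 1))
  ring <- cells == 1 & nuc == 0
  expect_equal(lt$l_c == 1, ring)

  stray <- nuc; stray[1, 1] <- 9L
  expect_error(labels_from_segmentation(label_map(cells, 1),
                                        label_map(stray, 1)),
               "9")
})

test_that("models round-trip through serialization", {
  set.seed(88)
  m <- build_network()
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  px <- matrix(runif(176 * 176), 176, 176)
  expect_identical(wholecellseg:::unet_predict(m$ptr, px),
                   wholecellseg:::unet_predict(m2$ptr, px))
  unlink(f)
})
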