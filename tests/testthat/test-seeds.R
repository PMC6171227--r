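test_that("LoG response is zero on constants and peaks at the matching scale", {
  p <- matrix(0.4, 64, 64)
  resp <- multiscale_log(p, 0.65)
  expect_lt(max(resp), 1e-8)  # zero up to FFT filtering noise

  # Gaussian blob of scale s: the per-scale response at the center is
  # maximal for the sigma closest to s (scale-normalized LoG property)
  n <- 81; s <- 6
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  blob <- exp(-((rr - 41)^2 + (cc - 41)^2) / (2 * s^2))
  params <- seed_params(log_sigmas_um = c(2, 4, 6, 9, 13) * 0.65)
  resp <- multiscale_log(blob, 0.65, params, return_stack = TRUE)
  stack <- attr(resp, "stack")
  center_by_scale <- stack[41, 41, ]
  expect_equal(which.max(center_by_scale), 3)  # sigma = 6 px
  expect_equal(as.vector(which(resp == max(resp), arr.ind = TRUE)[1, ]),
               c(41, 41))
})

test_that("two blobs of different sizes give one local maximum each", {
  n <- 96
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  p <- exp(-((rr - 30)^2 + (cc - 30)^2) / (2 * 4^2)) +
    exp(-((rr - 65)^2 + (cc - 65)^2) / (2 * 8^2))
  p <- p / max(p)
  resp <- multiscale_log(p, 0.65,
                         seed_params(log_sigmas_um = c(3, 5, 8, 12) * 0.65))
  is_max <- function(r, c) resp[r, c] == max(resp[(r - 2):(r + 2),
                                                  (c - 2):(c + 2)])
  expect_true(is_max(30, 30))
  expect_true(is_max(65, 65))
  bad <- seed_params()
  bad$log_sigmas_um <- numeric(0)
  expect_error(multiscale_log(p, 0.65, bad), "empty")
})

test_that("sensitivity maps to the documented threshold index", {
  set.seed(51)
  resp <- matrix(c(rexp(900, 1), runif(124, 5, 9)), 32, 32)
  m60 <- binarize_sensitivity(resp, seed_params(sensitivity = 60))
  expect_equal(attr(m60, "index"), 3)  # third threshold of five
  m100 <- binarize_sensitivity(resp, seed_params(sensitivity = 100))
  expect_equal(attr(m100, "index"), 5)
  m1 <- binarize_sensitivity(resp, seed_params(sensitivity = 0.5))
  expect_equal(attr(m1, "index"), 1)  # clamped at the lowest threshold
  # nesting: lower sensitivity gives a superset mask
  m20 <- binarize_sensitivity(resp, seed_params(sensitivity = 20))
  expect_true(all(m60 <= m20))
  expect_true(all(m100 <= m60))
})

test_that("split_nuclei separates overlapping disks and respects its mask", {
  # pixel size 1 um: the default h = 3 um is 3 px, matching the geometry
  params <- seed_params()
  one <- matrix(0L, 40, 40)
  one[disk_mask(40, 40, 20, 20, 10)] <- 1L
  lab1 <- split_nuclei(one, 1, params)
  expect_equal(n_objects(lab1), 1)
  expect_true(all((lab1$labels > 0) == (one > 0)))

  # centers 16 px apart at radius 10: distance peaks 10, waist ~6, depth 4
  two <- matrix(0L, 40, 56)
  two[disk_mask(40, 56, 20, 20, 10)] <- 1L
  two[disk_mask(40, 56, 20, 36, 10)] <- 1L
  lab2 <- split_nuclei(two, 1, params)
  expect_equal(n_objects(lab2), 2)
  expect_true(all((lab2$labels > 0) == (two > 0)))
  expect_equal(lab2$labels[20, 18], lab2$labels[20, 14])
  expect_false(lab2$labels[20, 20] == lab2$labels[20, 36])

  # shallow dumbbell: peak-to-saddle depth 2 < h = 3 stays one object
  shallow <- matrix(0L, 30, 60)
  shallow[disk_mask(30, 60, 15, 18, 7)] <- 1L
  shallow[disk_mask(30, 60, 15, 40, 7)] <- 1L
  shallow[10:20, 18:40] <- 1L  # neck half-width 5 vs peaks 7
  lab3 <- split_nuclei(shallow, 1, params)
  expect_equal(n_objects(lab3), 1)

  empty <- split_nuclei(matrix(0L, 10, 10), 0.65)
  expect_equal(n_objects(empty), 0)
})

test_that("watershed label count equals the marker count", {
  set.seed(52)
  for (rep in 1:5) {
    mask <- matrix(0L, 48, 48)
    for (i in 1:3)
      mask[disk_mask(48, 48, runif(1, 12, 36), runif(1, 12, 36),
                     runif(1, 5, 9))] <- 1L
    D <- as.matrix(EBImage::distmap(mask))
    markers <- wholecellseg:::cpp_hminima_markers(-D, 3, mask)
    lab <- wholecellseg:::cpp_watershed(-D, markers, mask)
    expect_equal(sort(setdiff(unique(as.vector(lab)), 0L)),
                 seq_len(max(markers)))
  }
})

test_that("the seed pipeline recovers the exact count for well-separated nuclei", {
  set.seed(53)
  g <- generate_image(synth_config(n_cells = 12, touching_fraction = 0,
                                   seed = 530))
  lt <- labels_from_segmentation(g$cells, g$nuclei)
  seeds <- detect_seeds(lt$l_n, 0.65)
  expect_equal(n_objects(seeds), 12)
  tab <- seed_table(seeds)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$area_px > 0))
})
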