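test_that("enhancement is multiplicative, nonnegative and monotone", {
  set.seed(61)
  px <- matrix(runif(48 * 48, 0, 200), 48, 48)
  img <- image2d(px, 0.65)
  ones <- matrix(1, 48, 48)
  base <- enhance_cells(img, ones)
  expect_true(all(base >= 0))
  expect_equal(enhance_cells(img, matrix(0, 48, 48)), matrix(0, 48, 48))
  half <- matrix(0.5, 48, 48)
  expect_equal(enhance_cells(img, half), base * 0.5)

  brighter <- image2d(px + 50, 0.65)
  expect_true(all(enhance_cells(brighter, ones) >= base - 1e-9))
  expect_error(enhance_cells(img, matrix(1, 10, 10)), "differ")
})

test_that("background threshold selection minimizes the area mismatch", {
  # single plateau of known area: any isolating threshold matches exactly
  enh <- matrix(0, 60, 60)
  plateau <- disk_mask(60, 60, 30, 30, 15)
  enh[plateau] <- 100
  enh <- enh + matrix(runif(3600, 0, 1), 60, 60)
  a_star_px <- sum(plateau)
  p <- cell_params(expected_cell_area_um2 = a_star_px * 0.65^2)
  bg <- estimate_background(enh, 1, 0.65, p)
  expect_equal(sum(!bg), a_star_px)
  expect_equal(sort(unique(as.vector(bg[plateau]))), FALSE)

  # argmin property against every candidate on the documented grid
  set.seed(62)
  enh2 <- matrix(c(runif(1200, 0, 2), runif(800, 40, 60),
                   runif(500, 150, 200)), 50, 50)
  n_seeds <- 4
  pp <- cell_params(expected_cell_area_um2 = 120)
  bg2 <- estimate_background(enh2, n_seeds, 0.65, pp)
  a_star <- attr(bg2, "expected_area_px")
  th <- multilevel_otsu(enh2, 3)
  grid <- seq(th[1], th[3], length.out = 64)
  areas <- vapply(grid, function(t) sum(enh2 >= t), numeric(1))
  expect_true(all(abs(attr(bg2, "foreground_area_px") - a_star) <=
                    abs(areas - a_star)))
  expect_error(estimate_background(enh2, 0, 0.65, pp), "no seeds")
})

test_that("segment_cells partitions a merged region between its two seeds", {
  # two bright gaussian mounds joined in one foreground region
  n <- 48
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  enh <- 100 * exp(-((rr - 24)^2 + (cc - 15)^2) / 60) +
    100 * exp(-((rr - 24)^2 + (cc - 33)^2) / 60)
  seeds <- matrix(0L, n, n)
  seeds[24, 15] <- 1L; seeds[24, 33] <- 2L
  bg <- enh < 5
  cells <- segment_cells(enh, label_map(seeds, 0.65), bg)
  expect_setequal(setdiff(unique(as.vector(cells$labels)), 0L), 1:2)
  expect_equal(cells$labels[24, 15], 1L)
  expect_equal(cells$labels[24, 33], 2L)
  # ridge between the mounds separates the labels along the midline
  expect_true(all(cells$labels[, 1:12][cells$labels[, 1:12] > 0] == 1L))
  expect_true(all(cells$labels[, 36:48][cells$labels[, 36:48] > 0] == 2L))
  # flood matches the independent frontier-scan implementation
  markers <- seeds; markers[bg] <- 3L
  ref <- oracle_watershed(-enh, markers, matrix(1L, n, n))
  ref[ref == 3L] <- 0L
  expect_identical(cells$labels, ref)

  expect_error(segment_cells(enh, label_map(matrix(0L, n, n), 0.65), bg),
               "empty seeds")
})

test_that("cell count equals seed count and labels are conserved", {
  set.seed(63)
  g <- generate_image(synth_config(n_cells = 15, seed = 631))
  lt <- labels_from_segmentation(g$cells, g$nuclei)
  seeds <- detect_seeds(lt$l_n, 0.65)
  enh <- enhance_cells(g$image, lt$l_c, cell_params())
  bg <- estimate_background(enh, n_objects(seeds), 0.65, cell_params())
  bg <- refine_background_marker(bg, seeds, cell_params()$
                                   expected_cell_area_um2 / 0.65^2)
  cells <- suppressMessages(segment_cells(enh, seeds, bg))
  expect_setequal(setdiff(unique(as.vector(cells$labels)), 0L),
                  setdiff(unique(as.vector(seeds$labels)), 0L))
  # watershed partition: every seed lies inside its own cell
  sm <- seeds$labels
  expect_true(all(cells$labels[sm > 0] == sm[sm > 0]))
})

test_that("shrinking the background marker never shrinks a cell", {
  n <- 40
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  enh <- 80 * exp(-((rr - 20)^2 + (cc - 20)^2) / 80)
  seeds <- matrix(0L, n, n); seeds[20, 20] <- 1L
  big_bg <- enh < 20
  small_bg <- enh < 5  # smaller threshold -> smaller background mask
  a_big <- sum(segment_cells(enh, label_map(seeds, 1), big_bg)$labels == 1)
  a_small <- sum(segment_cells(enh, label_map(seeds, 1), small_bg)$labels == 1)
  expect_gte(a_small, a_big)
})
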