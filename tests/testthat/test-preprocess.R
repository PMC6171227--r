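test_that("top-hat removes constants and flat backgrounds, keeps small features", {
  img <- image2d(matrix(500, 40, 40), 0.65)
  expect_equal(tophat_correct(img, 16)$pixels, matrix(0, 40, 40))

  set.seed(3)
  px <- matrix(10, 64, 64)
  px[disk_mask(64, 64, 32, 32, 10)] <- 100  # 20-px disk on flat background
  img <- image2d(px, 0.65)
  out <- tophat_correct(img, 50)  # kernel much larger than the disk
  expect_equal(out$pixels, px - oracle_opening(px, 50), tolerance = 1e-12)
  expect_true(all(abs(out$pixels[disk_mask(64, 64, 32, 32, 8)] - 90) < 1e-9))
  expect_true(all(abs(out$pixels[!disk_mask(64, 64, 32, 32, 11)]) < 1e-9))
})

test_that("top-hat suppresses a full-frame ramp but keeps a bright disk", {
  rr <- matrix(seq_len(80), 80, 80)
  px <- rr * 0.5 + 20
  px[disk_mask(80, 80, 40, 40, 6)] <- px[disk_mask(80, 80, 40, 40, 6)] + 60
  img <- image2d(px, 0.65)
  out <- tophat_correct(img, 41)
  expect_equal(out$pixels, px - oracle_opening(px, 41), tolerance = 1e-12)
  off_disk <- !disk_mask(80, 80, 40, 40, 8)
  expect_lt(mean(out$pixels[off_disk]), 1e-6 + 0.5 * 41 / 2)  # ramp residual
  expect_gt(max(out$pixels[disk_mask(80, 80, 40, 40, 4)]), 50)
})

test_that("opening is anti-extensive and the top-hat idempotent", {
  set.seed(11)
  px <- matrix(runif(60 * 60, 0, 100), 60, 60)
  img <- image2d(px, 1)
  out1 <- tophat_correct(img, 15)
  expect_true(all(out1$pixels <= px + 1e-12))
  expect_true(all(out1$pixels >= -1e-12))
  out2 <- tophat_correct(out1, 15)
  expect_equal(out2$pixels, out1$pixels, tolerance = 1e-10)
})

test_that("top-hat rejects kernels larger than the image and tiny kernels", {
  img <- image2d(matrix(1, 30, 30), 1)
  expect_error(tophat_correct(img, 200), "larger than both")
  expect_error(tophat_correct(img, 2), "at least 3")
})

test_that("resampling honors the reference pixel size contract", {
  set.seed(5)
  img <- image2d(matrix(runif(256 * 256, 0, 1000), 256, 256), 0.65)
  expect_identical(resample_to_reference(img), img)  # already at reference

  img20x <- image2d(matrix(runif(256 * 256, 0, 1000), 256, 256), 0.325)
  out <- resample_to_reference(img20x)
  expect_equal(dim(out$pixels), c(128L, 128L))
  expect_equal(out$pixel_size_um, 0.65)
  # area averaging: block means and intensity range preserved
  expect_equal(out$pixels[1, 1], mean(img20x$pixels[1:2, 1:2]))
  expect_gte(min(out$pixels), min(img20x$pixels))
  expect_lte(max(out$pixels), max(img20x$pixels))

  cimg <- image2d(matrix(7.5, 64, 64), 0.325)
  expect_equal(resample_to_reference(cimg)$pixels, matrix(7.5, 32, 32))

  coarse <- image2d(matrix(1, 16, 16), 1.3)
  expect_warning(out <- resample_to_reference(coarse), "upsampling")
  expect_identical(out$pixels, coarse$pixels)
})

test_that("resampling twice to the same target is the identity", {
  set.seed(6)
  img <- image2d(matrix(runif(128 * 128), 128, 128), 0.325)
  once <- resample_to_reference(img)
  twice <- resample_to_reference(once)
  expect_identical(twice$pixels, once$pixels)
})
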