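test_that("grayscale conversion passes single channels through and averages RGB", {
  m <- rand_image(6, 8)
  expect_identical(to_grayscale(m), m)
  rgb <- array(0, dim = c(1, 1, 3))
  rgb[1, 1, ] <- c(30, 60, 90)
  expect_equal(to_grayscale(rgb)[1, 1], 60)
  expect_error(to_grayscale(array(0, dim = c(2, 2, 4))), "format")
})

test_that("grayscale intensity survives a disk round trip", {
  dn <- matrix(round(runif(48 * 64, 0, 65535)), 48, 64)
  f <- tempfile(fileext = ".tif")
  write_specklegram(dn, f, bit_depth = 16)
  back <- to_grayscale(read_specklegram(f))
  expect_equal(back, dn)
  unlink(f)
})

test_that("fixed-scale normalization divides by digital full scale", {
  img <- matrix(c(0, 16383, 32767, 65535), 2, 2)
  out <- normalize_unit(img, "fixed", bit_depth = 16)
  expect_equal(as.vector(out), c(0, 16383, 32767, 65535) / 65535,
               tolerance = 1e-4)
  expect_equal(as.vector(out), c(0, 0.25, 0.5, 1), tolerance = 1e-4)
  expect_equal(normalize_unit(matrix(0, 3, 3), "fixed"), matrix(0, 3, 3))
})

test_that("normalization to unit range is idempotent and min-max rejects constants", {
  img <- matrix(runif(20), 4, 5)
  expect_equal(normalize_unit(img, "fixed", bit_depth = 1) * 1,
               img, tolerance = 1e-12)  # unit full scale (2^1 - 1 = 1)
  expect_error(normalize_unit(matrix(5, 2, 2), "minmax"), "zero-range")
})

test_that("block-mean downsampling has the documented shape and exact means", {
  big <- matrix(runif(1280 * 1024), 1024, 1280)
  small <- downsample(big, 4)
  expect_equal(dim(small), c(256, 320))
  expect_lt(abs(mean(small) - mean(big)), 1e-12)

  blocks <- matrix(c(1, 2, 5, 8,
                     3, 4, 6, 7,
                     10, 20, 50, 60,
                     30, 40, 70, 80), 4, 4, byrow = TRUE)
  expect_equal(downsample(blocks, 4)[1, 1], mean(blocks))
  expect_equal(downsample(blocks, 2),
               matrix(c(mean(c(1, 2, 3, 4)), mean(c(10, 20, 30, 40)),
                        mean(c(5, 8, 6, 7)), mean(c(50, 60, 70, 80))), 2, 2))
  expect_equal(downsample(matrix(7, 8, 8), 4), matrix(7, 2, 2))
  expect_error(downsample(matrix(0, 5, 8), 4), "shape")
})

test_that("the full chain keeps values in [0,1] and is deterministic", {
  dn <- matrix(round(runif(32 * 32, 0, 65535)), 32, 32)
  a <- preprocess_image(dn, factor = 4)
  b <- preprocess_image(dn, factor = 4)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(dim(a), c(8, 8))
})
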