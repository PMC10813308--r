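# independent two-pass reference implementation used as oracle
zncc_loop <- function(a, b) {
  ma <- 0; mb <- 0; n <- length(a)
  for (i in seq_len(n)) { ma <- ma + a[i] / n; mb <- mb + b[i] / n }
  num <- 0; ea <- 0; eb <- 0
  for (i in seq_len(n)) {
    num <- num + (a[i] - ma) * (b[i] - mb)
    ea <- ea + (a[i] - ma)^2
    eb <- eb + (b[i] - mb)^2
  }
  num / sqrt(ea * eb)
}

test_that("self-correlation is exactly one", {
  img <- rand_image(12, 10, seed = 2)
  expect_equal(zncc(img, img), 1, tolerance = 1e-14)
})

test_that("ZNCC is invariant to positive affine brightness changes", {
  a <- rand_image(9, 9, seed = 3)
  b <- rand_image(9, 9, seed = 4)
  z <- zncc(a, b)
  expect_equal(zncc(a, 2 * a + 5), 1, tolerance = 1e-12)
  for (alpha in c(0.1, 3, 250)) {
    expect_equal(zncc(a, alpha * b + 17), z, tolerance = 1e-12)
  }
})

test_that("a reversed ramp is exactly anticorrelated", {
  i0 <- matrix(c(0, 1, 2, 3), 2, 2)
  i1 <- matrix(c(3, 2, 1, 0), 2, 2)
  expect_equal(zncc(i0, i1), -1, tolerance = 1e-14)
})

test_that("negation flips the sign of the correlation", {
  a <- rand_image(7, 11, seed = 5)
  b <- rand_image(7, 11, seed = 6)
  expect_equal(zncc(a, -b + 3), -zncc(a, b), tolerance = 1e-12)
})

test_that("ZNCC matches the brute-force two-pass oracle on random pairs", {
  for (i in 1:10) {
    a <- rand_image(8, 8, seed = i)
    b <- rand_image(8, 8, seed = i + 50)
    expect_equal(zncc(a, b), zncc_loop(a, b), tolerance = 1e-12)
  }
})

test_that("ZNCC is symmetric and bounded in [-1, 1]", {
  for (i in 1:25) {
    a <- rand_image(6, 9, seed = i)
    b <- rand_image(6, 9, seed = i + 100)
    z <- zncc(a, b)
    expect_identical(z, zncc(b, a))
    expect_true(z >= -1 && z <= 1)
  }
})

test_that("shape mismatch and zero variance are explicit errors", {
  expect_error(zncc(rand_image(4, 4), rand_image(4, 5)), "dimension")
  expect_error(zncc(matrix(2, 4, 4), rand_image(4, 4)),
               "undefined-correlation")
})

test_that("the correlation curve groups probes by concentration", {
  cfg <- tiny_config(dataset = list(per_class = 4L))
  ds <- generate_dataset(cfg, seed = 6)
  ref <- ds$reference$intensity
  curve <- correlation_curve(ref, ds$manifest, images = ds$images)
  expect_s3_class(curve, "correlation_curve")
  expect_equal(nrow(curve), length(cfg$dataset$panel))
  expect_equal(curve$concentration_ng_per_ml, sort(cfg$dataset$panel))
  expect_true(all(curve$n == 4))
  expect_true(all(abs(curve$mean_zncc) <= 1))
  expect_true(all(diff(curve$mean_zncc) < 0))  # decreasing with concentration
})

test_that("probes identical to the reference give mean ZNCC 1", {
  ref <- rand_image(10, 10, seed = 1)
  man <- data.frame(id = c("a", "b"), path = NA,
                    concentration_ng_per_ml = c(1, 5),
                    split = "train", seed = 1)
  curve <- correlation_curve(ref, man, images = list(a = ref, b = ref))
  expect_equal(curve$mean_zncc, c(1, 1), tolerance = 1e-14)
})
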