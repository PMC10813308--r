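# deterministic well-separated toy classes for training tests; the class
# prototypes are fixed so different seeds give different noise draws of the
# same task (train/validation/test must share the prototypes)
toy_classes <- function(n, K = 3, h = 16, w = 16, noise = 0.03, seed = 1) {
  set.seed(99)
  proto <- array(runif(h * w * K), dim = c(h, w, K))
  set.seed(seed)
  y <- rep(seq_len(K), length.out = n)
  x <- array(0, dim = c(h, w, 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- proto[, , y[i]] + matrix(rnorm(h * w, 0, noise), h, w)
  }
  list(x = x, y = y)
}

toy_cfg <- function(...) {
  args <- utils::modifyList(
    list(input_shape = c(16L, 16L), panel = c(1, 10, 100),
         conv_filters = c(4L, 8L), dense_width = 16L,
         batch_size = 16L, epochs = 30L, patience = 30L, seed = 1L),
    list(...))
  do.call(cnn_config, args)
}

test_that("the output layer spans the panel and lies on the simplex", {
  cfg <- cnn_config(input_shape = c(32L, 32L))
  m <- build_model(cfg)
  expect_equal(cfg$class_count, 9)
  probs <- predict_proba(m, array(runif(32 * 32 * 3), dim = c(32, 32, 1, 3)))
  expect_equal(nrow(probs), 9)
  expect_equal(colSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("initialization is reproducible from the seed", {
  m1 <- build_model(toy_cfg())
  m2 <- build_model(toy_cfg())
  expect_identical(m1$params, m2$params)
  m3 <- build_model(toy_cfg(seed = 2L))
  expect_false(identical(m1$params, m3$params))
})

test_that("incompatible input shapes raise an architecture error", {
  expect_error(cnn_config(input_shape = c(4L, 4L),
                          conv_filters = c(4L, 8L, 16L)),
               "architecture")
})

test_that("numerical gradients match backpropagation", {
  cfg <- cnn_config(input_shape = c(8L, 8L), panel = c(1, 10),
                    conv_filters = c(2L), dense_width = 4L, seed = 3L)
  m <- build_model(cfg)
  set.seed(4)
  x <- array(runif(8 * 8 * 2), dim = c(8, 8, 1, 2))
  y <- c(1L, 2L)
  lg <- specklegram:::cnn_loss_grads(m, x, y)
  eps <- 1e-6
  for (nm in c("conv1_W", "dense_W", "out_b")) {
    th <- m$params[[nm]]
    for (i in c(1, length(th))) {
      mp <- m; mp$params[[nm]][i] <- th[i] + eps
      mm <- m; mm$params[[nm]][i] <- th[i] - eps
      num <- (specklegram:::cnn_loss_grads(mp, x, y)$loss -
                specklegram:::cnn_loss_grads(mm, x, y)$loss) / (2 * eps)
      expect_equal(unname(lg$grads[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("training separable classes reaches perfect validation accuracy", {
  tr <- toy_classes(60, seed = 1)
  va <- toy_classes(30, seed = 2)
  m <- train_cnn(build_model(toy_cfg()), tr$x, tr$y, va$x, va$y)
  h <- m$history
  expect_lte(nrow(h), 30)
  expect_equal(h$val_accuracy[nrow(h)], 1.0)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("training is reproducible and splits must be non-empty", {
  tr <- toy_classes(30, seed = 1)
  va <- toy_classes(12, seed = 2)
  m1 <- train_cnn(build_model(toy_cfg(epochs = 2L)), tr$x, tr$y, va$x, va$y)
  m2 <- train_cnn(build_model(toy_cfg(epochs = 2L)), tr$x, tr$y, va$x, va$y)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  empty <- array(0, dim = c(16, 16, 1, 0))
  expect_error(train_cnn(build_model(toy_cfg()), tr$x, tr$y, empty,
                         integer()), "data")
})

test_that("expected-value decoding is the probability-weighted panel mean", {
  panel <- c(1, 5, 10, 20, 30, 50, 100, 500, 1000)
  onehot <- replace(numeric(9), 4, 1)
  expect_equal(decode_concentration(onehot, panel), 20)
  expect_equal(decode_concentration(rep(1 / 9, 9), panel),
               sum(panel) / 9)  # 190.666...
  expect_equal(decode_concentration(rep(1 / 9, 9), panel), 190 + 2 / 3,
               tolerance = 1e-12)
  half <- replace(numeric(9), 1:2, 0.5)
  expect_equal(decode_concentration(half, panel), 3)
  expect_error(decode_concentration(numeric(4), panel), "dimension")
})

test_that("decoded concentrations always lie inside the panel span", {
  m <- build_model(toy_cfg())
  x <- array(runif(16 * 16 * 20, 0, 1), dim = c(16, 16, 1, 20))
  pred <- predict_concentration(m, x)
  expect_true(all(pred$decoded_ng_per_ml >= 1))
  expect_true(all(pred$decoded_ng_per_ml <= 100))
})

test_that("evaluation reports errors, regression line and confusion", {
  tr <- toy_classes(60, seed = 1)
  va <- toy_classes(30, seed = 2)
  te <- toy_classes(30, seed = 3)
  m <- train_cnn(build_model(toy_cfg()), tr$x, tr$y, va$x, va$y)
  conc <- c(1, 10, 100)[te$y]
  ev <- evaluate_cnn(m, te$x, conc, ids = sprintf("t%02d", 1:30))
  expect_s3_class(ev, "cnn_evaluation")
  expect_gte(ev$max_rel_error_pct, 0)
  expect_true(is.finite(ev$slope))
  expect_equal(sum(ev$confusion), 30)
  expect_error(evaluate_cnn(m, te$x, rep(0, 30)), "domain")
})

test_that("perfect one-hot predictions give zero error and unit slope", {
  panel <- c(1, 10, 100)
  probs <- diag(3)[, c(1, 2, 3, 1)]
  chat <- decode_concentration(probs, panel)
  truth <- panel[c(1, 2, 3, 1)]
  expect_equal(chat, truth)
  fit <- lm(chat ~ truth)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-9)
})
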