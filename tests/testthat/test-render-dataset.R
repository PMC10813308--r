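test_that("rendering is bit-identical for identical (c, config, seed)", {
  cfg <- tiny_config()
  scene <- build_scene(cfg, seed = 4)
  a <- render_specklegram(10, seed = 7, scene = scene)
  b <- render_specklegram(10, seed = 7, scene = scene)
  d <- render_specklegram(10, seed = 8, scene = scene)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, d$intensity))
})

test_that("without the camera stage the render is the pure mode superposition", {
  cfg <- tiny_config()
  scene <- build_scene(cfg, seed = 4)
  img <- render_specklegram(20, seed = 1, scene = scene, camera = FALSE)
  st <- apply_concentration(scene$baseline, scene$dose, 20,
                            coupling = scene$coupling)
  ref <- field_to_intensity(synthesize_field(st, scene$basis))
  expect_identical(img$intensity, ref$intensity)
})

test_that("far-apart concentrations decorrelate more than repeated frames", {
  cfg <- tiny_config(modes = list(M = 20L))
  scene <- build_scene(cfg, seed = 2)
  i1a <- render_specklegram(1, seed = 1, scene = scene)$intensity
  i1b <- render_specklegram(1, seed = 2, scene = scene)$intensity
  i1000 <- render_specklegram(1000, seed = 1, scene = scene)$intensity
  expect_lt(zncc(i1a, i1000), zncc(i1a, i1b))
})

test_that("dataset counts, stratification and manifest layout are exact", {
  cfg <- tiny_config(dataset = list(per_class = 8L))
  ds <- generate_dataset(cfg, seed = 5)
  man <- ds$manifest
  expect_equal(nrow(man), 3 * 8)
  expect_equal(as.vector(table(man$split)[c("train", "validation", "test")]),
               c(12, 6, 6))
  per_class <- table(man$concentration_ng_per_ml, man$split)
  expect_true(all(per_class[, "train"] == 4))
  expect_true(all(per_class[, "validation"] == 2))
  expect_true(all(per_class[, "test"] == 2))
  expect_false(anyDuplicated(man$id) > 0)
  expect_equal(length(ds$images), nrow(man))
})

test_that("regenerating a dataset under a fixed seed is byte-identical on disk", {
  cfg <- tiny_config(dataset = list(per_class = 2L))
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  generate_dataset(cfg, seed = 3, dir = d1)
  generate_dataset(cfg, seed = 3, dir = d2)
  f1 <- sort(list.files(d1, pattern = "\\.tif$"))
  expect_identical(f1, sort(list.files(d2, pattern = "\\.tif$")))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("written images round-trip through the manifest", {
  cfg <- tiny_config(dataset = list(per_class = 2L))
  d <- file.path(tempdir(), "ds_rt")
  ds <- generate_dataset(cfg, seed = 3, dir = d)
  man <- read_manifest(file.path(d, "manifest.csv"))
  expect_equal(man$id, ds$manifest$id)
  img <- read_specklegram(man$path[1])
  expect_equal(dim(img), c(cfg$grid$height, cfg$grid$width))
  expect_true(all(img == round(img)))
  unlink(d, recursive = TRUE)
})
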