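# Small-scale configurations and fixtures shared across tests.

# A miniature pipeline config: 64 x 48 grid, 8 modes, 3 classes, 6 frames
# per class. Fast enough for end-to-end unit tests.
tiny_config <- function(...) {
  cfg <- default_config()
  cfg$grid$width <- 64L
  cfg$grid$height <- 48L
  cfg$modes$M <- 8L
  cfg$dataset$panel <- c(1, 50, 1000)
  cfg$dataset$per_class <- 6L
  cfg$dataset$split <- list(train = 0.5, validation = 0.25, test = 0.25)
  cfg$cnn$downsample_factor <- 2L
  cfg$cnn$conv_filters <- c(4L, 8L)
  cfg$cnn$dense_width <- 16L
  cfg$cnn$epochs <- 2L
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], mods[[nm]])
  cfg
}

tiny_grid <- function(width = 64L, height = 48L) {
  simulation_grid(width = width, height = height)
}

# deterministic pseudo-random image
rand_image <- function(h, w, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}
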