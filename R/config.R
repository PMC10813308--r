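#' Default pipeline configuration
#'
#' Returns the full nested configuration of the pipeline with the shipped
#' dose-response calibration. In desk-scale mode (the default) specklegrams
#' are rendered directly on the 320 x 256 post-downsampling grid and the CNN
#' consumes a further 4x block-mean reduction to 80 x 64; full mode renders
#' 1280 x 1024 frames that the preprocessing chain reduces to 320 x 256.
#'
#' Seeds left `NULL` are derived from the run seed by stable hashing
#' ([fan_seed()]), so a single global seed reproduces the whole pipeline
#' while any stage seed can be pinned individually.
#'
#' @param desk_scale logical; reduced-resolution configuration suitable for a
#'   single CPU.
#' @return a nested list of class `speckle_config`.
#' @export
default_config <- function(desk_scale = TRUE) {
  cfg <- list(
    seed = 1L,
    grid = list(
      width = if (desk_scale) 320L else 1280L,
      height = if (desk_scale) 256L else 1024L,
      pixel_pitch_um = 5.3, tip_to_camera_mm = 5, exposure_ms = 6
    ),
    modes = list(M = 30L, basis = "smooth", seed = NULL),
    coupling = list(h_scale = 0.05, convention = "relax", seed = NULL),
    dose = list(
      response_max = 0.93, half_sat_K = 100, hill_h = 1,
      beta_range = 1.5, coupling_scale = 1, jitter_sd = 0.005, seed = NULL
    ),
    camera = list(
      bit_depth = 16L, shot_noise = TRUE, read_noise_sd = 100,
      full_scale_electrons = 20000
    ),
    dataset = list(
      panel = c(1, 5, 10, 20, 30, 50, 100, 500, 1000),
      per_class = 100L,
      split = list(train = 0.5, validation = 0.25, test = 0.25),
      seed = NULL
    ),
    preprocess = list(
      downsample_factor = if (desk_scale) 1L else 4L,
      norm = "fixed"
    ),
    zncc = list(reference = "baseline"),
    calibration = list(c_min = 1, c_max = 50),
    cnn = list(
      downsample_factor = 4L,
      conv_filters = c(16L, 32L, 64L), kernel = 3L, pool = 2L,
      dense_width = 128L,
      learning_rate = 1e-3, batch_size = 32L,
      epochs = 30L, patience = 5L, seed = NULL
    )
  )
  structure(cfg, class = c("speckle_config", "list"))
}

# strict recursive merge: every key in `user` must exist in `defaults`
merge_config <- function(defaults, user, path = character()) {
  if (is.null(user)) return(defaults)
  if (!is.list(user) || !is.list(defaults)) return(user)
  nm <- names(user)
  if (length(user) && (is.null(nm) || any(!nzchar(nm)))) {
    return(user)  # unnamed lists (e.g. panels) replace wholesale
  }
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown)) {
    stop_with("config", "unknown configuration key: %s",
              paste(c(path, unknown[1]), collapse = "$"))
  }
  for (k in nm) {
    # `defaults[k] <- list(...)` keeps keys whose merged value is NULL
    # (e.g. unset stage seeds) instead of deleting them
    defaults[k] <- list(merge_config(defaults[[k]], user[[k]], c(path, k)))
  }
  defaults
}

#' Load a pipeline configuration from YAML
#'
#' Reads a (possibly partial or empty) YAML file, fills unset keys with
#' [default_config()] values and rejects unknown keys by name.
#'
#' @param path path to a YAML file.
#' @param desk_scale defaults baseline, see [default_config()].
#' @return a validated `speckle_config`.
#' @export
load_config <- function(path, desk_scale = TRUE) {
  if (!file.exists(path)) stop_with("config", "no such config file: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- merge_config(default_config(desk_scale), user)
  validate_config(structure(cfg, class = c("speckle_config", "list")))
}

#' Write a configuration to YAML
#'
#' @param config a `speckle_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' @param config a `speckle_config`.
#' @return the config, invisibly usable; errors name the offending key.
#' @export
validate_config <- function(config) {
  simulation_grid(config$grid$width, config$grid$height,
                  config$grid$pixel_pitch_um)
  if (config$modes$M < 1) stop_with("config", "modes$M must be >= 1")
  if (config$dose$hill_h <= 0) stop_with("config", "dose$hill_h must be > 0")
  if (config$dose$jitter_sd < 0) {
    stop_with("config", "dose$jitter_sd must be >= 0")
  }
  camera_model(config$camera$bit_depth, config$camera$shot_noise,
               config$camera$read_noise_sd, config$camera$full_scale_electrons)
  ds <- config$dataset
  if (!length(ds$panel)) stop_with("config", "dataset$panel must be non-empty")
  if (anyDuplicated(ds$panel)) {
    stop_with("config", "dataset$panel concentrations must be unique")
  }
  if (ds$per_class < 1) stop_with("config", "dataset$per_class must be >= 1")
  sp <- unlist(ds$split)
  if (!setequal(names(sp), c("train", "validation", "test"))) {
    stop_with("config", "dataset$split must name train, validation, test")
  }
  if (abs(sum(sp) - 1) > 1e-9) {
    stop_with("config", "dataset$split fractions must sum to 1")
  }
  if (!config$preprocess$norm %in% c("fixed", "minmax")) {
    stop_with("config", "preprocess$norm must be 'fixed' or 'minmax'")
  }
  if (config$cnn$epochs < 1) stop_with("config", "cnn$epochs must be >= 1")
  config
}

config_hash <- function(config) digest::digest(unclass(config))
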