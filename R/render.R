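#' Build the static optical "scene" shared by all frames of one experiment
#'
#' Constructs, from a configuration and run seed, everything that is fixed
#' across frames: the orthonormal mode basis, the baseline mode state (the
#' fiber before analyte exposure), the coupling matrix, the dose-response
#' model with seeded per-mode sensitivities, and the exposure gain that maps
#' the noise-free baseline intensity to ~80% of digital full scale.
#'
#' @param config a `speckle_config` (see [default_config()]).
#' @param seed run seed; stage seeds left `NULL` in the config are derived
#'   from it with [fan_seed()].
#' @return an object of class `speckle_scene`.
#' @export
build_scene <- function(config, seed = config$seed) {
  validate_config(config)
  grid <- simulation_grid(config$grid$width, config$grid$height,
                          config$grid$pixel_pitch_um,
                          config$grid$tip_to_camera_mm,
                          config$grid$exposure_ms)
  M <- config$modes$M
  basis <- build_mode_basis(M, grid,
                            seed = config$modes$seed %||% fan_seed(seed, "modes"),
                            type = config$modes$basis)
  baseline <- random_mode_state(M, seed = fan_seed(seed, "baseline"))
  h <- coupling_matrix(M, config$coupling$h_scale,
                       seed = config$coupling$seed %||% fan_seed(seed, "coupling"))
  beta <- draw_mode_sensitivities(M, config$dose$beta_range,
                                  seed = config$dose$seed %||% fan_seed(seed, "dose"))
  dose <- dose_response_model(config$dose$response_max, config$dose$half_sat_K,
                              config$dose$hill_h, mode_sensitivities = beta,
                              coupling_scale = config$dose$coupling_scale)
  cam <- camera_model(config$camera$bit_depth, config$camera$shot_noise,
                      config$camera$read_noise_sd,
                      config$camera$full_scale_electrons)
  i0 <- field_to_intensity(synthesize_field(baseline, basis),
                           stage_tag = "baseline")
  gain <- 0.8 * (2^cam$bit_depth - 1) / max(i0$intensity)
  structure(
    list(grid = grid, basis = basis, baseline = baseline, coupling = h,
         dose = dose, camera = cam, gain = gain, config = config,
         seed = seed),
    class = "speckle_scene"
  )
}

#' @export
print.speckle_scene <- function(x, ...) {
  cat(sprintf("<speckle_scene> M = %d on %d x %d, seed %d\n",
              x$basis$M, x$grid$width, x$grid$height, x$seed))
  invisible(x)
}

#' Render the noise-free 0 ng/mL reference specklegram
#'
#' The pre-exposure baseline frame on the digital-number scale, used as the
#' fixed reference for ZNCC demodulation.
#'
#' @param scene a [build_scene()] result.
#' @return a `speckle_image` tagged `"reference"`.
#' @export
render_reference <- function(scene) {
  img <- field_to_intensity(synthesize_field(scene$baseline, scene$basis),
                            stage_tag = "reference")
  speckle_image(img$intensity * scene$gain, stage_tag = "reference")
}

#' Render one specklegram at a given concentration
#'
#' Applies the dose-response perturbation to the baseline mode state,
#' optionally adds a small seeded per-mode phase jitter (frame-to-frame
#' drift), superposes the modal fields, converts to intensity, scales to the
#' digital-number range and applies the camera noise/quantization model.
#' Bit-identical for identical `(c, config, seed)`.
#'
#' @param c concentration in ng/mL.
#' @param config a `speckle_config`; ignored when `scene` is supplied.
#' @param seed frame seed controlling jitter and camera noise.
#' @param scene optional precomputed [build_scene()] (shared across frames).
#' @param camera logical; when `FALSE` the raw interference intensity is
#'   returned (no jitter, no exposure scaling, no noise) — exactly the
#'   [synthesize_field()] + [field_to_intensity()] composition.
#' @return a `speckle_image`.
#' @export
render_specklegram <- function(c, config = default_config(), seed = 1L,
                               scene = NULL, camera = TRUE) {
  if (is.null(scene)) scene <- build_scene(config, seed = config$seed)
  state <- apply_concentration(scene$baseline, scene$dose, c,
                               coupling = scene$coupling,
                               convention = scene$config$coupling$convention)
  if (!camera) {
    img <- field_to_intensity(synthesize_field(state, scene$basis),
                              concentration = c, seed = seed)
    return(img)
  }
  jsd <- scene$config$dose$jitter_sd
  if (jsd > 0) {
    jit <- with_seed(fan_seed(seed, "jitter"),
                     stats::rnorm(state$M, 0, jsd))
    state <- mode_state(state$powers, state$phases + jit)
  }
  img <- field_to_intensity(synthesize_field(state, scene$basis),
                            concentration = c, seed = seed)
  img$intensity <- img$intensity * scene$gain
  add_camera_noise(img, scene$camera, seed = fan_seed(seed, "noise"))
}

split_counts <- function(split, per_class) {
  n_tr <- round(split$train * per_class)
  n_va <- round(split$validation * per_class)
  n_te <- per_class - n_tr - n_va
  if (n_te < 0) stop_with("config", "split fractions incompatible with per_class")
  c(train = n_tr, validation = n_va, test = n_te)
}

#' Generate a labeled specklegram dataset
#'
#' Renders `per_class` frames for every concentration of the panel from one
#' shared optical scene. Replicate frames of a class share the deterministic
#' concentration perturbation but differ in seeded phase jitter and camera
#' noise. The split is stratified exactly per class in replicate order
#' (replicates are exchangeable by construction). With the default
#' configuration this yields 900 images in 9 classes split 450/225/225.
#'
#' When `dir` is given, images are written as 16-bit grayscale TIFF together
#' with `manifest.csv` and a `config.yaml` provenance echo; otherwise the
#' quantized images are returned in memory.
#'
#' @param config a `speckle_config`.
#' @param seed run seed (drives the scene and all frame seeds).
#' @param dir optional output directory (created if needed).
#' @return a list of class `speckle_dataset` with elements `manifest`
#'   (data.frame: id, path, concentration_ng_per_ml, split, seed), `images`
#'   (named list of digital-number matrices, `NULL` when written to disk),
#'   `reference` (the 0 ng/mL reference image), `scene`, and `dir`.
#' @export
generate_dataset <- function(config = default_config(), seed = config$seed,
                             dir = NULL) {
  validate_config(config)
  scene <- build_scene(config, seed = seed)
  panel <- sort(config$dataset$panel)
  per_class <- config$dataset$per_class
  counts <- split_counts(config$dataset$split, per_class)
  tags <- rep(names(counts), counts)
  write_images <- !is.null(dir)
  if (write_images) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  n <- length(panel) * per_class
  ids <- character(n); paths <- character(n); concs <- numeric(n)
  splits <- character(n); seeds <- integer(n)
  images <- if (write_images) NULL else vector("list", n)
  k <- 0L
  for (ci in seq_along(panel)) {
    conc <- panel[ci]
    state <- apply_concentration(scene$baseline, scene$dose, conc,
                                 coupling = scene$coupling,
                                 convention = config$coupling$convention)
    for (j in seq_len(per_class)) {
      k <- k + 1L
      fseed <- fan_seed(seed, "frame", ci, j)
      st <- state
      jsd <- config$dose$jitter_sd
      if (jsd > 0) {
        jit <- with_seed(fan_seed(fseed, "jitter"),
                         stats::rnorm(st$M, 0, jsd))
        st <- mode_state(st$powers, st$phases + jit)
      }
      img <- field_to_intensity(synthesize_field(st, scene$basis),
                                concentration = conc, seed = fseed)
      img$intensity <- img$intensity * scene$gain
      img <- add_camera_noise(img, scene$camera,
                              seed = fan_seed(fseed, "noise"))
      id <- sprintf("conc%s_rep%03d", formatC(conc, format = "fg"), j)
      ids[k] <- id; concs[k] <- conc; splits[k] <- tags[j]; seeds[k] <- fseed
      if (write_images) {
        p <- file.path(dir, paste0(id, ".tif"))
        write_specklegram(img$intensity, p,
                          bit_depth = config$camera$bit_depth)
        paths[k] <- p
      } else {
        paths[k] <- NA_character_
        images[[k]] <- img$intensity
      }
    }
  }
  if (anyDuplicated(ids)) stop_with("manifest", "duplicate image identifiers")
  manifest <- data.frame(id = ids, path = paths,
                         concentration_ng_per_ml = concs, split = splits,
                         seed = seeds, stringsAsFactors = FALSE)
  if (!write_images) names(images) <- ids
  reference <- render_reference(scene)
  if (write_images) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    save_config(config, file.path(dir, "config.yaml"))
    write_specklegram(reference$intensity, file.path(dir, "reference.tif"),
                      bit_depth = config$camera$bit_depth)
  }
  structure(
    list(manifest = manifest, images = images, reference = reference,
         scene = scene, dir = dir),
    class = "speckle_dataset"
  )
}

#' @export
print.speckle_dataset <- function(x, ...) {
  cat(sprintf("<speckle_dataset> %d images, %d classes, splits: %s\n",
              nrow(x$manifest),
              length(unique(x$manifest$concentration_ng_per_ml)),
              paste(capture_counts(x$manifest$split), collapse = ", ")))
  invisible(x)
}

capture_counts <- function(split) {
  tb <- table(factor(split, levels = c("train", "validation", "test")))
  sprintf("%s=%d", names(tb), as.integer(tb))
}
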